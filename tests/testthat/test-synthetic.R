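test_that("generator configuration is validated", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(group_mix = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(generator_config(lga_or = c(2, 3, 1.5, 2.8)), "group 1 = 1")
  expect_error(
    generator_config(exclusion_rates = c(pih = 0.5, no_weight = 0.6,
      no_gct = 0, no_ogtt = 0, one_value = 0, gdm = 0, elsewhere = 0)),
    "sum to < 1"
  )
})

test_that("generation is reproducible and n = 0 yields an empty schema table", {
  empty <- generate_cohort(generator_config(n = 0))
  expect_equal(nrow(empty), 0)
  expect_gt(ncol(empty), 20)

  cfg <- generator_config(n = 500, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
})

test_that("a noiseless generator with unit ratios round-trips to FAOR = 1", {
  cohort <- generate_cohort(quiet_config(n = 80, seed = 12))
  prep <- prepare_study_data(cohort)
  d <- prep$data
  expect_equal(nrow(d), 80) # no exclusions planted
  expect_true(all(d$has_biometry_mid))
  expect_equal(d$faor_lmp, rep(1, 80), tolerance = 1e-4)
  expect_equal(d$faor_bpd, rep(1, 80), tolerance = 1e-4)
  expect_equal(d$faor_fl, rep(1, 80), tolerance = 1e-4)
  expect_equal(d$faor_near_lmp, rep(1, 80), tolerance = 1e-4)
})

test_that("planted glycemic categories survive re-classification exactly", {
  cfg <- generator_config(n = 4000, seed = 55)
  cohort <- generate_cohort(cfg)
  truth <- attr(cohort, "truth")
  classifiable <- !is.na(cohort$gct_mgdl)
  cls <- classify_glycemic_status(
    cohort$gct_mgdl[classifiable],
    tibble::tibble(
      fasting = cohort$ogtt_fasting_mgdl, h1 = cohort$ogtt_1h_mgdl,
      h2 = cohort$ogtt_2h_mgdl, h3 = cohort$ogtt_3h_mgdl
    )[classifiable, ],
    faor_config()
  )
  cat_cls <- truth$category[classifiable]
  expect_true(all(cls$status[cat_cls == "gdm"] == "GDM"))
  expect_true(all(cls$status[cat_cls == "one_value"] == "one_value_abnormality"))
  expect_true(all(cls$status[cat_cls == "no_ogtt"] == "unclassifiable"))
  expect_true(all(cls$status[cat_cls %in% c("none", "elsewhere", "pih")] %in%
    c("NGT_screen_negative", "NGT_ogtt")))
})

test_that("exclusion counts fall inside binomial 99% bounds of the planted rates", {
  cfg <- generator_config(n = 20000, seed = 77)
  cohort <- generate_cohort(cfg)
  truth <- attr(cohort, "truth")
  counts <- table(factor(truth$category,
    levels = c(names(cfg$exclusion_rates), "none")))
  for (nm in names(cfg$exclusion_rates)) {
    lo <- qbinom(0.005, cfg$n, cfg$exclusion_rates[[nm]])
    hi <- qbinom(0.995, cfg$n, cfg$exclusion_rates[[nm]])
    expect_gte(counts[[nm]], lo)
    expect_lte(counts[[nm]], hi)
  }
})

test_that("planted mid-gestation FAO prevalence is 10% at level 0.9", {
  cfg <- generator_config(n = 10000, seed = 88)
  cohort <- generate_cohort(cfg)
  truth <- attr(cohort, "truth")
  expect_equal(mean(truth$fao_true), 0.1, tolerance = 1 / sqrt(cfg$n))
})

test_that("planted truth mirrors the configured links and degenerates correctly", {
  # All outcome slopes at 1 and a flat ratio model: every planted OR is 1.
  flat <- generator_config(
    lga_or = c(1, 1, 1, 1), macro_or = c(1, 1, 1, 1),
    cesarean_or = c(1, 1, 1, 1),
    fao_or = c(lga = 1, macro = 1, cesarean = 1),
    age_mean = rep(31, 4), age_sd = rep(0, 4),
    bmi_mean = rep(21, 4), bmi_sd = rep(0, 4),
    gain_dx_mean = rep(7, 4), gain_dx_sd = rep(0, 4),
    gct_mean = rep(110, 4), gct_sd = rep(0, 4)
  )
  # Groups 2/4 need BMI >= 25 truncation, so silence it by zero slopes too.
  flat$bmi_mean <- c(21, 27, 21, 27)
  tr <- planted_truth(flat)
  expect_equal(unname(tr$lga_or), rep(1, 4))
  expect_equal(unname(tr$fao_or[["lga"]]), 1)
  # Ratio distribution identical across groups when BMI has zero slope.
  flat2 <- flat
  flat2$faor_model$bmi <- 0
  tr2 <- planted_truth(flat2)
  expect_equal(unname(tr2$fao_group_or), rep(1, 4), tolerance = 1e-9)

  # A configured group-2 odds ratio is echoed by construction.
  cfg <- generator_config(lga_or = c(1, 3, 1.5, 2.8))
  expect_equal(planted_truth(cfg)$lga_or[2], 3)
  expect_equal(planted_truth(cfg)$expected_exclusions[["gdm"]],
    cfg$n * cfg$exclusion_rates[["gdm"]])
})

test_that("semi-analytic FAO group probabilities match a large-sample simulation", {
  # The derivation treats the within-group ratio as Gaussian; age and BMI
  # are truncated normals, so the tail probabilities carry a small skew
  # error on top of Monte-Carlo noise. Absolute agreement within 0.01 on
  # probabilities near 0.10 checks the moment propagation end to end.
  cfg <- generator_config(n = 200000, seed = 123)
  tr <- planted_truth(cfg)
  cohort <- generate_cohort(cfg)
  truth <- attr(cohort, "truth")
  sim_p <- tapply(truth$fao_true, truth$group, mean)
  expect_true(all(abs(unname(sim_p) - tr$fao_group_prob) < 0.01))
  # And the ordering of group risks is reproduced exactly.
  expect_equal(order(sim_p), order(tr$fao_group_prob))
})

test_that("cohort CSV round trip preserves the table; bad files are rejected", {
  cfg <- generator_config(n = 200, seed = 31)
  cohort <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  plain <- cohort
  attr(plain, "truth") <- NULL
  attr(plain, "fao_cut") <- NULL
  expect_equal(back, plain, tolerance = 1e-12)

  bad <- cohort
  bad$infant_sex[3] <- "unknown"
  write_cohort(bad, path)
  expect_error(read_cohort(path), "infant_sex")

  readr::write_csv(tibble::tibble(x = 1), path)
  suppressWarnings(expect_error(read_cohort(path), "missing columns"))
})

test_that("macrosomia implies LGA in generated cohorts (coupled links)", {
  cohort <- generate_cohort(generator_config(n = 5000, seed = 61))
  truth <- attr(cohort, "truth")
  expect_true(all(truth$lga_true[truth$macro_true]))
  # And the labels the pipeline derives from birth weight agree with the
  # planted flags (the generator draws weights consistently).
  lab <- label_outcomes(
    cohort$birth_weight_g, cohort$ga_delivery_days, cohort$infant_sex
  )
  expect_equal(lab$lga, truth$lga_true)
  expect_equal(lab$macrosomia, truth$macro_true)
})
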