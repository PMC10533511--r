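test_that("glycemic classification follows the two-step cascade", {
  # Screen-negative: no OGTT required.
  res <- classify_glycemic_status(120)
  expect_equal(as.character(res$status), "NGT_screen_negative")
  expect_true(is.na(res$n_abnormal))

  # Screen-positive without OGTT is unclassifiable.
  res <- classify_glycemic_status(150)
  expect_equal(as.character(res$status), "unclassifiable")

  # Exactly one exceedance (1-h 185 >= 180).
  res <- classify_glycemic_status(150, c(90, 185, 150, 135))
  expect_equal(as.character(res$status), "one_value_abnormality")
  expect_equal(res$n_abnormal, 1L)

  # Three exceedances (fasting, 1-h, 2-h) diagnose GDM.
  res <- classify_glycemic_status(150, c(100, 190, 160, 120))
  expect_equal(as.character(res$status), "GDM")
  expect_equal(res$n_abnormal, 3L)

  expect_error(classify_glycemic_status(NA_real_), "exclusion")
})

test_that("classification equals a brute-force count over all 16 abnormality patterns", {
  cc <- faor_config()$cc
  lo <- c(cc$fasting - 5, cc$h1 - 5, cc$h2 - 5, cc$h3 - 5)
  hi <- c(cc$fasting, cc$h1, cc$h2, cc$h3) # inclusive boundary
  patterns <- expand.grid(f = 0:1, h1 = 0:1, h2 = 0:1, h3 = 0:1)
  panel <- tibble::tibble(
    fasting = ifelse(patterns$f == 1, hi[1], lo[1]),
    h1 = ifelse(patterns$h1 == 1, hi[2], lo[2]),
    h2 = ifelse(patterns$h2 == 1, hi[3], lo[3]),
    h3 = ifelse(patterns$h3 == 1, hi[4], lo[4])
  )
  res <- classify_glycemic_status(rep(150, 16), panel)
  n_expected <- rowSums(patterns)
  expect_equal(res$n_abnormal, as.integer(n_expected))
  expect_equal(
    as.character(res$status),
    ifelse(n_expected == 0, "NGT_ogtt",
      ifelse(n_expected == 1, "one_value_abnormality", "GDM")
    )
  )
})

test_that("exclusion cascade drops planted records stage by stage and telescopes", {
  cfg <- quiet_config(n = 100, seed = 3)
  cohort <- generate_cohort(cfg)
  # Plant exclusions by hand on known rows.
  cohort$pih_before_24gw[1:5] <- TRUE
  cohort$prepreg_weight_kg[6:8] <- NA
  cohort$gct_mgdl[9:10] <- NA
  cc <- faor_config()$cc
  cohort$gct_mgdl[11:14] <- 150
  cohort$ogtt_fasting_mgdl[11:14] <- cc$fasting + 5
  cohort$ogtt_1h_mgdl[11:14] <- cc$h1 + 5
  cohort$ogtt_2h_mgdl[11:14] <- 120
  cohort$ogtt_3h_mgdl[11:14] <- 120
  cohort$delivered_elsewhere[15] <- TRUE

  res <- apply_exclusions(cohort)
  expect_equal(nrow(res$included), 85)
  expect_equal(res$log$n_excluded,
    c(5L, 3L, 2L, 0L, 0L, 4L, 1L))
  # Telescoping: each stage's n_in equals the previous n_out.
  expect_equal(res$log$n_in[-1], res$log$n_out[-nrow(res$log)])
  expect_equal(res$log$n_out[nrow(res$log)], nrow(res$included))
})

test_that("empty cohorts pass through the cascade with an all-zero log", {
  res <- apply_exclusions(generate_cohort(generator_config(n = 0)))
  expect_equal(nrow(res$included), 0)
  expect_true(all(res$log$n_in == 0))
  expect_true(all(res$log$n_excluded == 0))
})

test_that("counts-based flow reproduces a published-style cascade exactly", {
  flow <- screening_flow_counts(
    n_total = 7820, n_pih = 25, n_no_weight = 28, n_no_gct = 198,
    n_no_ogtt = 47, n_one_value = 250, n_gdm = 384, n_elsewhere = 167
  )
  expect_equal(attr(flow, "n_screened"), 7569L)
  expect_equal(attr(flow, "n_ngt"), 6888L)
  expect_equal(attr(flow, "n_included"), 6721L)
  expect_equal(flow$n_in[-1], flow$n_out[-nrow(flow)])
  expect_error(
    screening_flow_counts(10, 5, 6, 0, 0, 0, 0, 0),
    "exceed"
  )
})

test_that("subgroup assignment partitions on inclusive boundaries", {
  expect_equal(as.character(assign_subgroup(31.0, 20.0)), "G1")
  expect_equal(as.character(assign_subgroup(35.0, 25.0)), "G4") # both inclusive
  expect_equal(as.character(assign_subgroup(36.0, 21.0)), "G3")
  expect_equal(as.character(assign_subgroup(30.0, 25.0)), "G2")
  expect_true(is.na(assign_subgroup(NA, 20)))

  # Partition property: every point maps to exactly one group; sizes sum.
  set.seed(5)
  age <- runif(500, 20, 45)
  bmi <- runif(500, 16, 35)
  g <- assign_subgroup(age, bmi)
  expect_false(anyNA(g))
  expect_equal(sum(table(g)), 500L)
})

test_that("HOMA indices match the closed forms, with the singular case flagged", {
  res <- homa_indices(90, 7.2)
  expect_equal(res$homa_ir, 1.6, tolerance = 1e-9)
  expect_equal(res$homa_beta, 96, tolerance = 1e-9)

  res <- homa_indices(81, 5)
  expect_equal(res$homa_ir, 1.0, tolerance = 1e-9)
  expect_equal(res$homa_beta, 100, tolerance = 1e-9)

  # At 63 mg/dL the secretion index is undefined but IR is returned.
  res <- homa_indices(63, 5)
  expect_equal(res$homa_ir, 63 * 5 / 405, tolerance = 1e-9)
  expect_true(is.na(res$homa_beta))

  expect_error(homa_indices(-1, 5), "positive")

  # Vector inputs against the closed forms.
  g <- c(70, 85, 100, 120)
  i <- c(4, 6, 9, 14)
  res <- homa_indices(g, i)
  expect_equal(res$homa_ir, g * i / 405, tolerance = 1e-9)
  expect_equal(res$homa_beta, 360 * i / (g - 63), tolerance = 1e-9)
})

test_that("outcome labels use inclusive cutoffs and the matched reference cell", {
  ref <- tibble::tibble(
    ga_week = c(39L, 39L), sex = c("male", "female"), p90_g = c(3600, 3500)
  )
  lab <- label_outcomes(
    birth_weight_g = c(4000, 3600, 3500, 3600, 3100),
    ga_delivery_days = c(275, 275, 275, 275, 200),
    infant_sex = c("male", "male", "male", "female", "male"),
    lga_reference = ref
  )
  expect_equal(lab$macrosomia, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # At exactly the p90 cell the LGA flag is true (inclusive >=).
  expect_equal(lab$lga[1:4], c(TRUE, TRUE, FALSE, TRUE))
  # Delivery week outside the reference: LGA missing, macrosomia computed.
  expect_true(is.na(lab$lga[5]))
  expect_false(lab$macrosomia[5])
})
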