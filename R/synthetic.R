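# Synthetic pregnancy-cohort generator with planted, retrievable ground
# truth. The generator emulates the statistical structure the analysis
# assumes -- four maternal age x BMI subgroups, a linear model for the
# abdominal overgrowth ratio on clinical factors, biometry produced by the
# forward growth charts plus measurement noise, the GCT/OGTT screening
# cascade with planted exclusion categories, and logistic links from
# subgroup and fetal-abdominal-obesity status to the delivery outcomes --
# so that every pipeline stage can be tested end to end without patient
# data.

#' Generator configuration
#'
#' All distributions are configurable; the defaults describe a plausible
#' East-Asian hospital cohort of normal-glucose-tolerance pregnancies:
#' about 63% young/non-obese, 3% young/obese, 31% older/non-obese and 3%
#' older/obese women, with subgroup-specific age, BMI, weight-gain and
#' screening-glucose distributions, a linear model for the mid-gestation
#' GA-AC/GA-LMP ratio with mean near 1.028 and SD near 0.04, and logistic
#' outcome links whose subgroup odds ratios (LGA 1/3.0/1.5/2.8, macrosomia
#' 1/2.5/0.95/1.1, primary cesarean 1/1.3/1.35/1.3) echo the pattern of
#' published NGT cohorts.
#'
#' @param n cohort size.
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param group_mix probabilities of the four subgroups (young/non-obese,
#'   young/obese, older/non-obese, older/obese); must sum to 1.
#' @param age_mean,age_sd per-group maternal age (years); groups 1-2 are
#'   truncated below 35, groups 3-4 at or above 35.
#' @param bmi_mean,bmi_sd per-group pre-pregnancy BMI (kg/m^2); truncated
#'   below/at-or-above 25 analogously.
#' @param gain_dx_mean,gain_dx_sd per-group weight gain (kg) from
#'   pre-pregnancy to the screening visit.
#' @param gain_term_extra_mean,gain_term_extra_sd additional gain to near
#'   term (truncated at 0).
#' @param gct_mean,gct_sd per-group 50-g GCT glucose (mg/dL).
#' @param faor_model linear model of the mid-gestation GA-AC/GA-LMP ratio:
#'   named list `intercept`, `age`, `bmi`, `gain`, `gct`, `sd` (residual).
#' @param head_ga_scale,head_ga_scale_sd multiplicative offset of the
#'   head/femur ultrasound gestational age relative to dates (mean ~1.018:
#'   scans systematically read slightly ahead of menstrual dating).
#' @param biometry_noise_sd_mm additive measurement noise on each biometry
#'   value, mm.
#' @param biometry_missing_rate fraction with no mid-gestation biometry.
#' @param near_missing_rate fraction with no near-term biometry.
#' @param faor_persist autoregression of the near-term ratio on the
#'   mid-gestation ratio (1 = full persistence).
#' @param faor_near_sd innovation SD of the near-term ratio.
#' @param lga_or,macro_or,cesarean_or per-group outcome odds ratios
#'   (group 1 is the reference and must be 1).
#' @param lga_base,macro_base,cesarean_base baseline outcome probabilities
#'   in group 1 without fetal abdominal obesity.
#' @param fao_or named vector: multiplicative odds effect of mid-gestation
#'   fetal abdominal obesity on `lga`, `macro`, `cesarean`.
#' @param fao_level percentile level defining planted FAO status (0.90).
#' @param exclusion_rates named probabilities for the planted exclusion
#'   categories `pih`, `no_weight`, `no_gct`, `no_ogtt`, `one_value`,
#'   `gdm`, `elsewhere` (the remainder is retained).
#' @param primipara_prob per-group probability of first birth.
#' @param repeat_cesarean_prob probability of a repeat cesarean among
#'   multiparae not having a primary cesarean.
#' @param male_prob probability of a male infant.
#' @param ga_delivery_mean per-group mean gestational age at delivery
#'   (days), SD `ga_delivery_sd`, truncated to 34-42 completed weeks.
#' @param ga_delivery_sd SD of gestational age at delivery (days).
#' @param bw_intercept,bw_slope_per_week,bw_male_shift,bw_sd birth-weight
#'   model: mean `bw_intercept + bw_slope_per_week * (week - 39) +
#'   bw_male_shift * male`, used below the LGA reference percentile.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(
    n = 20000,
    seed = NULL,
    group_mix = c(0.63, 0.03, 0.31, 0.03),
    age_mean = c(31.0, 31.2, 37.2, 37.5),
    age_sd = c(2.4, 2.4, 2.2, 2.3),
    bmi_mean = c(20.0, 27.5, 20.5, 27.4),
    bmi_sd = c(1.9, 2.6, 1.9, 2.4),
    gain_dx_mean = c(7.7, 5.8, 7.6, 5.3),
    gain_dx_sd = c(3.1, 4.9, 3.2, 4.2),
    gain_term_extra_mean = 5.4,
    gain_term_extra_sd = 2.0,
    gct_mean = c(109.9, 116.2, 114.3, 118.9),
    gct_sd = c(21.0, 19.6, 20.9, 23.1),
    faor_model = list(
      intercept = 0.928, age = 0.0015, bmi = 0.0015,
      gain = 0.0008, gct = 0.00012, sd = 0.036
    ),
    head_ga_scale = 1.018,
    head_ga_scale_sd = 0.030,
    biometry_noise_sd_mm = 1.5,
    biometry_missing_rate = 0.24,
    near_missing_rate = 0.10,
    faor_persist = 0.5,
    faor_near_sd = 0.025,
    lga_or = c(1, 3.0, 1.5, 2.8),
    macro_or = c(1, 2.5, 0.95, 1.1),
    cesarean_or = c(1, 1.3, 1.35, 1.3),
    lga_base = 0.035,
    macro_base = 0.012,
    cesarean_base = 0.19,
    fao_or = c(lga = 4.5, macro = 4.5, cesarean = 1.35),
    fao_level = 0.90,
    exclusion_rates = c(
      pih = 0.0032, no_weight = 0.0036, no_gct = 0.0253,
      no_ogtt = 0.0060, one_value = 0.0320, gdm = 0.0491,
      elsewhere = 0.0214
    ),
    primipara_prob = c(0.776, 0.670, 0.584, 0.504),
    repeat_cesarean_prob = 0.15,
    male_prob = 0.51,
    ga_delivery_mean = c(274, 272, 272, 269),
    ga_delivery_sd = 10,
    bw_intercept = 3250,
    bw_slope_per_week = 100,
    bw_male_shift = 80,
    bw_sd = 350) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$group_mix) - 1) > 1e-8) abort("`group_mix` must sum to 1.")
  if (any(cfg$group_mix < 0)) abort("`group_mix` must be non-negative.")
  for (nm in c("age_sd", "bmi_sd", "gain_dx_sd", "gct_sd")) {
    if (any(cfg[[nm]] < 0)) abort(sprintf("`%s` must be >= 0.", nm))
  }
  if (cfg$faor_model$sd < 0 || cfg$biometry_noise_sd_mm < 0) {
    abort("noise standard deviations must be >= 0.")
  }
  rates <- cfg$exclusion_rates
  needed <- c("pih", "no_weight", "no_gct", "no_ogtt", "one_value", "gdm", "elsewhere")
  if (!all(needed %in% names(rates))) {
    abort(sprintf("`exclusion_rates` needs: %s", paste(needed, collapse = ", ")))
  }
  if (any(rates < 0) || sum(rates) >= 1) {
    abort("`exclusion_rates` must be non-negative and sum to < 1.")
  }
  for (nm in c("lga_or", "macro_or", "cesarean_or")) {
    if (length(cfg[[nm]]) != 4L || cfg[[nm]][1] != 1 || any(cfg[[nm]] <= 0)) {
      abort(sprintf("`%s` must be 4 positive odds ratios with group 1 = 1.", nm))
    }
  }
  structure(cfg, class = c("generator_config", "list"))
}

# Draw OGTT panels with a prescribed number of abnormal values, so that the
# planted glycemic category survives re-classification exactly.
draw_ogtt <- function(n, pattern = c("normal", "one_value", "gdm"), cc) {
  pattern <- match.arg(pattern)
  below <- function(th, mean, sd) rtnorm(n, mean, sd, upper = th - 1e-6)
  above <- function(th, mean, sd) rtnorm(n, mean, sd, lower = th)
  out <- tibble::tibble(
    fasting = below(cc$fasting, 80.5, 6.3),
    h1 = below(cc$h1, 150, 20),
    h2 = below(cc$h2, 125, 18),
    h3 = below(cc$h3, 100, 18)
  )
  if (pattern == "one_value") {
    out$h1 <- above(cc$h1, 185, 10)
  } else if (pattern == "gdm") {
    out$fasting <- above(cc$fasting, 100, 5)
    out$h1 <- above(cc$h1, 195, 12)
    out$h2 <- above(cc$h2, 165, 10)
  }
  out
}

#' Generate a synthetic pregnancy cohort
#'
#' Produces one row per pregnancy in the same CSV schema the analysis
#' pipeline reads (see [read_cohort()]). Mid-gestation scans fall uniformly
#' in 24-28 weeks; the fetus's "abdominal" gestational age is the dating
#' gestational age times the planted overgrowth ratio, and the abdominal
#' circumference is the forward growth chart evaluated there plus
#' measurement noise, so that inverting the chart in the pipeline recovers
#' the planted ratio up to noise. OGTT panels exist only for screen-positive
#' women, with the planted glycemic category enforced. Delivery outcomes are
#' drawn from logistic links on subgroup and planted FAO status, with birth
#' weights drawn consistently with the LGA reference percentile and the
#' 4000-g macrosomia cutoff.
#'
#' @param config a [generator_config()].
#' @param charts optional named list of growth charts (`bpd`, `ac`, `fl`);
#'   defaults to the shipped synthetic charts.
#' @param lga_reference optional LGA reference table; defaults to the
#'   shipped synthetic reference.
#' @return a cohort tibble; the per-record planted state (true subgroup,
#'   true ratios, true FAO flag) is attached as attribute `"truth"`.
#' @export
generate_cohort <- function(config = generator_config(), charts = NULL,
                            lga_reference = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(charts)) {
    charts <- lapply(setNames(CHART_KINDS, CHART_KINDS), default_growth_chart)
  }
  if (is.null(lga_reference)) lga_reference <- load_lga_reference()
  n <- config$n
  if (n == 0) {
    return(empty_cohort())
  }

  group <- sample.int(4L, n, replace = TRUE, prob = config$group_mix)
  age <- rtnorm(n, config$age_mean[group], config$age_sd[group],
    lower = ifelse(group >= 3, 35, -Inf),
    upper = ifelse(group >= 3, Inf, 35 - 1e-9)
  )
  bmi <- rtnorm(n, config$bmi_mean[group], config$bmi_sd[group],
    lower = ifelse(group %in% c(2L, 4L), 25, 14),
    upper = ifelse(group %in% c(2L, 4L), Inf, 25 - 1e-9)
  )
  height <- rnorm(n, 1.61, 0.05)
  prepreg_weight <- bmi * height^2
  gain_dx <- rnorm(n, config$gain_dx_mean[group], config$gain_dx_sd[group])
  gain_term <- gain_dx + rtnorm(n, config$gain_term_extra_mean,
    config$gain_term_extra_sd,
    lower = 0
  )
  gct <- rtnorm(n, config$gct_mean[group], config$gct_sd[group], lower = 40)

  # Planted exclusion categories (mutually exclusive).
  rates <- config$exclusion_rates
  category <- sample(
    c(names(rates), "none"), n,
    replace = TRUE, prob = c(unname(rates), 1 - sum(rates))
  )
  # Categories that require a positive screen get a GCT redrawn above the
  # screening threshold.
  force_pos <- category %in% c("no_ogtt", "one_value", "gdm")
  gct[force_pos] <- rtnorm(sum(force_pos),
    config$gct_mean[group[force_pos]], config$gct_sd[group[force_pos]],
    lower = 140
  )

  fm <- config$faor_model
  faor_mid <- fm$intercept + fm$age * age + fm$bmi * bmi +
    fm$gain * gain_dx + fm$gct * gct + rnorm(n, 0, fm$sd)
  faor_near <- 1 + config$faor_persist * (faor_mid - 1) +
    rnorm(n, 0, config$faor_near_sd)

  vr_lo <- 98
  vr_hi <- 301
  clamp <- function(x) pmin(pmax(x, vr_lo), vr_hi)
  noise <- function(m) m + rnorm(length(m), 0, config$biometry_noise_sd_mm)

  ga_mid <- runif(n, 24 * 7, 28 * 7)
  head_scale_mid <- rnorm(n, config$head_ga_scale, config$head_ga_scale_sd)
  fl_scale_mid <- rnorm(n, config$head_ga_scale, config$head_ga_scale_sd)
  ac_mid <- noise(expected_biometry(charts$ac, clamp(ga_mid * faor_mid)))
  bpd_mid <- noise(expected_biometry(charts$bpd, clamp(ga_mid * head_scale_mid)))
  fl_mid <- noise(expected_biometry(charts$fl, clamp(ga_mid * fl_scale_mid)))

  ga_near <- runif(n, 36 * 7, 38 * 7)
  head_scale_near <- rnorm(n, config$head_ga_scale, config$head_ga_scale_sd)
  fl_scale_near <- rnorm(n, config$head_ga_scale, config$head_ga_scale_sd)
  ac_near <- noise(expected_biometry(charts$ac, clamp(ga_near * faor_near)))
  bpd_near <- noise(expected_biometry(charts$bpd, clamp(ga_near * head_scale_near)))
  fl_near <- noise(expected_biometry(charts$fl, clamp(ga_near * fl_scale_near)))

  mid_missing <- runif(n) < config$biometry_missing_rate
  near_missing <- runif(n) < config$near_missing_rate

  # Planted FAO status: at/above the cohort's own percentile of the
  # mid-gestation ratio.
  fao_cut <- unname(quantile(faor_mid, config$fao_level, type = 7))
  fao_true <- faor_mid >= fao_cut

  # Outcomes from logistic links; a shared uniform couples macrosomia
  # inside LGA so both marginal odds ratios hold exactly.
  lg <- function(base, or_vec, fao_mult) {
    plogis(qlogis(base) + log(or_vec[group]) + log(fao_mult) * fao_true)
  }
  p_lga <- lg(config$lga_base, config$lga_or, config$fao_or[["lga"]])
  p_macro <- pmin(
    lg(config$macro_base, config$macro_or, config$fao_or[["macro"]]),
    p_lga
  )
  u <- runif(n)
  macro <- u < p_macro
  lga <- u < p_lga
  p_pcs <- lg(config$cesarean_base, config$cesarean_or, config$fao_or[["cesarean"]])
  pcs <- runif(n) < p_pcs

  primipara <- runif(n) < config$primipara_prob[group]
  repeat_cs <- !primipara & !pcs & runif(n) < config$repeat_cesarean_prob
  delivery_mode <- ifelse(pcs, "primary_cesarean",
    ifelse(repeat_cs, "repeat_cesarean", "vaginal")
  )
  sex <- ifelse(runif(n) < config$male_prob, "male", "female")
  ga_del <- rtnorm(n, config$ga_delivery_mean[group], config$ga_delivery_sd,
    lower = 34 * 7, upper = 42 * 7 + 6.9
  )
  week <- floor(ga_del / 7)
  ref_key <- paste(lga_reference$ga_week, lga_reference$sex)
  p90 <- lga_reference$p90_g[match(paste(week, sex), ref_key)]
  mu_bw <- config$bw_intercept +
    config$bw_slope_per_week * (ga_del / 7 - 39) +
    config$bw_male_shift * (sex == "male")
  bw <- rtnorm(n, mu_bw, config$bw_sd, upper = p90 - 1)
  idx_lga <- which(lga & !macro)
  bw[idx_lga] <- p90[idx_lga] + runif(length(idx_lga)) * (3999 - p90[idx_lga])
  idx_macro <- which(macro)
  bw[idx_macro] <- 4000 + rexp(length(idx_macro), 1 / 180)

  # Glycemic panel consistent with the planted category.
  cc <- faor_config()$cc
  ogtt <- tibble::tibble(
    fasting = rep(NA_real_, n), h1 = NA_real_, h2 = NA_real_, h3 = NA_real_
  )
  natural_pos <- gct >= 140 & category %in% c("none", "elsewhere", "pih", "no_weight")
  if (any(natural_pos)) {
    ogtt[natural_pos, ] <- draw_ogtt(sum(natural_pos), "normal", cc)
  }
  ov <- category == "one_value"
  if (any(ov)) ogtt[ov, ] <- draw_ogtt(sum(ov), "one_value", cc)
  gd <- category == "gdm"
  if (any(gd)) ogtt[gd, ] <- draw_ogtt(sum(gd), "gdm", cc)
  has_ogtt <- !is.na(ogtt$fasting)
  insulin <- ifelse(has_ogtt, rlnorm(n, log(7), 0.4), NA_real_)
  hba1c <- ifelse(has_ogtt, rnorm(n, 5.0, 0.3), NA_real_)

  cohort <- tibble::tibble(
    id = sprintf("P%06d", seq_len(n)),
    age_years = age,
    height_m = height,
    prepreg_weight_kg = prepreg_weight,
    weight_at_dx_kg = prepreg_weight + gain_dx,
    weight_near_term_kg = prepreg_weight + gain_term,
    gct_mgdl = gct,
    ogtt_fasting_mgdl = ogtt$fasting,
    ogtt_1h_mgdl = ogtt$h1,
    ogtt_2h_mgdl = ogtt$h2,
    ogtt_3h_mgdl = ogtt$h3,
    hba1c_pct = hba1c,
    fasting_insulin_uUml = insulin,
    parity = ifelse(primipara, "primipara", "multipara"),
    pih_before_24gw = category == "pih",
    delivered_elsewhere = category == "elsewhere",
    ga_lmp_mid_days = ifelse(mid_missing, NA_real_, ga_mid),
    bpd_mid_mm = ifelse(mid_missing, NA_real_, bpd_mid),
    ac_mid_mm = ifelse(mid_missing, NA_real_, ac_mid),
    fl_mid_mm = ifelse(mid_missing, NA_real_, fl_mid),
    ga_lmp_near_days = ifelse(near_missing, NA_real_, ga_near),
    bpd_near_mm = ifelse(near_missing, NA_real_, bpd_near),
    ac_near_mm = ifelse(near_missing, NA_real_, ac_near),
    fl_near_mm = ifelse(near_missing, NA_real_, fl_near),
    birth_weight_g = bw,
    ga_delivery_days = ga_del,
    infant_sex = sex,
    delivery_mode = delivery_mode
  )
  # Planted missingness applied last so internal draws stay reproducible.
  cohort$prepreg_weight_kg[category == "no_weight"] <- NA_real_
  cohort$weight_at_dx_kg[category == "no_weight"] <- NA_real_
  cohort$gct_mgdl[category == "no_gct"] <- NA_real_

  attr(cohort, "truth") <- tibble::tibble(
    id = cohort$id,
    group = factor(paste0("G", group), levels = c("G1", "G2", "G3", "G4")),
    category = category,
    faor_mid = faor_mid,
    faor_near = faor_near,
    fao_true = fao_true,
    lga_true = lga,
    macro_true = macro,
    primary_cesarean_true = pcs
  )
  attr(cohort, "fao_cut") <- fao_cut
  cohort
}

empty_cohort <- function() {
  tibble::tibble(
    id = character(), age_years = numeric(), height_m = numeric(),
    prepreg_weight_kg = numeric(), weight_at_dx_kg = numeric(),
    weight_near_term_kg = numeric(), gct_mgdl = numeric(),
    ogtt_fasting_mgdl = numeric(), ogtt_1h_mgdl = numeric(),
    ogtt_2h_mgdl = numeric(), ogtt_3h_mgdl = numeric(),
    hba1c_pct = numeric(), fasting_insulin_uUml = numeric(),
    parity = character(), pih_before_24gw = logical(),
    delivered_elsewhere = logical(),
    ga_lmp_mid_days = numeric(), bpd_mid_mm = numeric(),
    ac_mid_mm = numeric(), fl_mid_mm = numeric(),
    ga_lmp_near_days = numeric(), bpd_near_mm = numeric(),
    ac_near_mm = numeric(), fl_near_mm = numeric(),
    birth_weight_g = numeric(), ga_delivery_days = numeric(),
    infant_sex = character(), delivery_mode = character()
  )
}

#' Planted ground truth implied by a generator configuration
#'
#' Derives, without simulation, the quantities the pipeline should recover:
#' the linear-model coefficients of the mid-gestation ratio, the per-group
#' outcome odds ratios and the FAO odds effect (all configured directly),
#' the expected exclusion counts, and the per-group marginal odds ratios of
#' fetal abdominal obesity. The latter follow from the ratio being Gaussian
#' within each subgroup: the subgroup mean and variance are propagated
#' through the linear model (using truncated-normal moments for age and
#' BMI), the population cutoff is the percentile of the four-component
#' normal mixture, and each subgroup's exceedance probability gives its
#' odds against group 1. This is a normal approximation -- the truncated
#' age/BMI components are mildly skewed -- accurate to well under 0.01 in
#' probability at the default settings.
#'
#' @param config a [generator_config()].
#' @return a list: `faor_coef`, `lga_or`, `macro_or`, `cesarean_or`,
#'   `fao_or`, `fao_group_or`, `fao_threshold`, `fao_group_prob`,
#'   `expected_exclusions`.
#' @export
planted_truth <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  fm <- config$faor_model
  mu <- numeric(4)
  v <- numeric(4)
  for (g in 1:4) {
    am <- tnorm_moments(config$age_mean[g], config$age_sd[g],
      lower = if (g >= 3) 35 else -Inf,
      upper = if (g >= 3) Inf else 35
    )
    bm <- tnorm_moments(config$bmi_mean[g], config$bmi_sd[g],
      lower = if (g %in% c(2, 4)) 25 else 14,
      upper = if (g %in% c(2, 4)) Inf else 25
    )
    mu[g] <- fm$intercept + fm$age * am$mean + fm$bmi * bm$mean +
      fm$gain * config$gain_dx_mean[g] + fm$gct * config$gct_mean[g]
    v[g] <- fm$age^2 * am$var + fm$bmi^2 * bm$var +
      fm$gain^2 * config$gain_dx_sd[g]^2 + fm$gct^2 * config$gct_sd[g]^2 +
      fm$sd^2
  }
  mix <- config$group_mix
  target <- config$fao_level
  if (all(v == 0)) {
    # Degenerate configuration: every subgroup ratio is deterministic.
    cut <- max(mu)
    p_g <- as.numeric(mu >= cut)
  } else {
    cdf <- function(x) sum(mix * pnorm(x, mu, sqrt(pmax(v, 1e-18))))
    lo <- min(mu - 8 * sqrt(max(v)))
    hi <- max(mu + 8 * sqrt(max(v)))
    cut <- uniroot(function(x) cdf(x) - target, c(lo, hi), tol = 1e-12)$root
    p_g <- 1 - pnorm(cut, mu, sqrt(pmax(v, 1e-18)))
  }
  odds <- p_g / (1 - p_g)
  list(
    faor_coef = fm,
    lga_or = config$lga_or,
    macro_or = config$macro_or,
    cesarean_or = config$cesarean_or,
    fao_or = config$fao_or,
    fao_group_or = odds / odds[1],
    fao_threshold = cut,
    fao_group_prob = p_g,
    expected_exclusions = config$n * config$exclusion_rates
  )
}

#' Write / read a cohort CSV
#'
#' The generator writes the same schema the pipeline reads, so generated
#' cohorts double as integration-test fixtures. Columns and units are
#' documented in the README.
#'
#' @param cohort a cohort tibble.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   a validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[names(empty_cohort())], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  schema <- empty_cohort()
  spec <- lapply(schema, function(col) {
    if (is.character(col)) readr::col_character()
    else if (is.logical(col)) readr::col_logical()
    else readr::col_double()
  })
  cohort <- readr::read_csv(path, col_types = do.call(readr::cols, spec))
  missing_cols <- setdiff(names(schema), names(cohort))
  if (length(missing_cols)) {
    abort(sprintf(
      "cohort CSV is missing columns: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad_parity <- !is.na(cohort$parity) &
    !cohort$parity %in% c("primipara", "multipara")
  if (any(bad_parity)) {
    abort(sprintf("invalid `parity` at row(s): %s",
      paste(head(which(bad_parity), 5), collapse = ", ")))
  }
  bad_sex <- !is.na(cohort$infant_sex) &
    !cohort$infant_sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort(sprintf("invalid `infant_sex` at row(s): %s",
      paste(head(which(bad_sex), 5), collapse = ", ")))
  }
  bad_mode <- !is.na(cohort$delivery_mode) &
    !cohort$delivery_mode %in% c("vaginal", "primary_cesarean", "repeat_cesarean")
  if (any(bad_mode)) {
    abort(sprintf("invalid `delivery_mode` at row(s): %s",
      paste(head(which(bad_mode), 5), collapse = ", ")))
  }
  cohort
}
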