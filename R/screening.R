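# The two-step gestational-diabetes screening cascade (universal 50-g GCT,
# confirmatory 100-g OGTT under the Carpenter-Coustan criteria), the
# exclusion flow that defines a normal-glucose-tolerance (NGT) cohort, the
# maternal age x pre-pregnancy BMI subgrouping, homeostasis-model indices
# and delivery-outcome labels.

GLYCEMIC_LEVELS <- c(
  "NGT_screen_negative", "NGT_ogtt", "one_value_abnormality",
  "GDM", "unclassifiable"
)

#' Classify glycemic status from the GCT/OGTT cascade
#'
#' Every woman is screened with a 50-g glucose challenge test (GCT) at 24-28
#' gestational weeks; those at or above the screen-positive threshold
#' (default 140 mg/dL) proceed to a 3-h 100-g oral glucose tolerance test
#' (OGTT). OGTT values are compared (inclusively) to the Carpenter-Coustan
#' thresholds, defaults 95/180/155/140 mg/dL at fasting/1 h/2 h/3 h:
#' zero exceedances is NGT, exactly one is a one-value abnormality, and two
#' or more diagnose gestational diabetes (GDM). A screen-positive woman
#' without an OGTT is unclassifiable.
#'
#' A missing GCT is an error here: such records belong in the exclusion
#' cascade ([apply_exclusions()]), not in classification.
#'
#' @param gct_mgdl 50-g GCT plasma glucose, mg/dL (vectorised; no `NA`).
#' @param ogtt OGTT panel: `NULL` (none performed), a numeric vector of
#'   length 4 `(fasting, h1, h2, h3)` for a single record, or a data frame
#'   with columns `fasting`, `h1`, `h2`, `h3` (`NA` rows = not performed).
#' @param config a [faor_config()]; uses `gct.threshold` and `cc.*`.
#' @return a tibble with columns `status` (factor with levels
#'   `NGT_screen_negative`, `NGT_ogtt`, `one_value_abnormality`, `GDM`,
#'   `unclassifiable`) and `n_abnormal` (count of OGTT exceedances, `NA`
#'   when no OGTT was performed).
#' @export
classify_glycemic_status <- function(gct_mgdl, ogtt = NULL,
                                     config = faor_config()) {
  if (anyNA(gct_mgdl)) {
    abort("missing GCT value: route the record through `apply_exclusions()` instead.")
  }
  n <- length(gct_mgdl)
  if (is.null(ogtt)) {
    panel <- tibble::tibble(
      fasting = rep(NA_real_, n), h1 = NA_real_, h2 = NA_real_, h3 = NA_real_
    )
  } else if (is.numeric(ogtt) && is.null(dim(ogtt))) {
    if (length(ogtt) != 4L || n != 1L) {
      abort("a numeric `ogtt` must have length 4 and match a single record.")
    }
    panel <- tibble::tibble(
      fasting = ogtt[1], h1 = ogtt[2], h2 = ogtt[3], h3 = ogtt[4]
    )
  } else {
    panel <- tibble::as_tibble(ogtt)
    if (!all(c("fasting", "h1", "h2", "h3") %in% names(panel))) {
      abort("`ogtt` data frame needs columns fasting, h1, h2, h3.")
    }
    if (nrow(panel) != n) {
      abort("`ogtt` must have one row per GCT value.")
    }
  }
  cc <- config$cc
  if (any(panel < 0, na.rm = TRUE)) {
    abort("OGTT glucose values must be positive.")
  }
  has_ogtt <- !is.na(panel$fasting) & !is.na(panel$h1) &
    !is.na(panel$h2) & !is.na(panel$h3)
  n_abn <- ifelse(has_ogtt,
    (panel$fasting >= cc$fasting) + (panel$h1 >= cc$h1) +
      (panel$h2 >= cc$h2) + (panel$h3 >= cc$h3),
    NA_integer_
  )
  screen_pos <- gct_mgdl >= config$gct$threshold
  status <- rep("NGT_screen_negative", n)
  status[screen_pos & !has_ogtt] <- "unclassifiable"
  status[screen_pos & has_ogtt & n_abn == 0] <- "NGT_ogtt"
  status[screen_pos & has_ogtt & n_abn == 1] <- "one_value_abnormality"
  status[screen_pos & has_ogtt & n_abn >= 2] <- "GDM"
  tibble::tibble(
    status = factor(status, levels = GLYCEMIC_LEVELS),
    n_abnormal = as.integer(ifelse(screen_pos, n_abn, NA_integer_))
  )
}

#' Apply the NGT-cohort exclusion cascade
#'
#' Applies, in order: pregnancy-induced hypertension before 24 gestational
#' weeks; missing maternal weight record; missing GCT result; then glycemic
#' classification, removing screen-positive women without an OGTT
#' (unclassifiable), one-value abnormalities and GDM; and finally delivery
#' at another hospital. Every stage logs how many records entered and how
#' many were excluded, so the log telescopes exactly to the included-cohort
#' size.
#'
#' @param cohort a cohort tibble in the schema of [generate_cohort()] /
#'   [read_cohort()].
#' @param config a [faor_config()].
#' @return a list with elements `included` (the NGT cohort tibble) and
#'   `log` (a tibble `stage`, `n_in`, `n_excluded`, `reason`).
#' @export
apply_exclusions <- function(cohort, config = faor_config()) {
  cohort <- tibble::as_tibble(cohort)
  log <- list()
  note <- function(stage, n_in, n_excluded, reason) {
    tibble::tibble(
      stage = stage, n_in = as.integer(n_in),
      n_excluded = as.integer(n_excluded), reason = reason
    )
  }
  drop_stage <- function(df, keep, stage, reason) {
    log[[length(log) + 1L]] <<- note(stage, nrow(df), sum(!keep), reason)
    df[keep, , drop = FALSE]
  }
  has <- function(col) col %in% names(cohort)

  pih <- if (has("pih_before_24gw")) {
    isTRUE_v(cohort$pih_before_24gw)
  } else {
    rep(FALSE, nrow(cohort))
  }
  cohort <- drop_stage(cohort, !pih, "pih",
    "pregnancy-induced hypertension before 24 GW")

  no_weight <- is.na(cohort$prepreg_weight_kg) | is.na(cohort$height_m)
  cohort <- drop_stage(cohort, !no_weight, "no_weight_record",
    "no maternal weight record")

  no_gct <- is.na(cohort$gct_mgdl)
  cohort <- drop_stage(cohort, !no_gct, "no_gct",
    "no 50-g GCT result")

  cls <- classify_glycemic_status(
    cohort$gct_mgdl,
    ogtt = tibble::tibble(
      fasting = cohort$ogtt_fasting_mgdl, h1 = cohort$ogtt_1h_mgdl,
      h2 = cohort$ogtt_2h_mgdl, h3 = cohort$ogtt_3h_mgdl
    ),
    config = config
  )
  cohort$glycemic_status <- cls$status

  cohort <- drop_stage(cohort, cohort$glycemic_status != "unclassifiable",
    "no_ogtt", "GCT-positive without OGTT (unclassifiable)")
  cohort <- drop_stage(cohort, cohort$glycemic_status != "one_value_abnormality",
    "one_value_abnormality", "one OGTT value at/above threshold")
  cohort <- drop_stage(cohort, cohort$glycemic_status != "GDM",
    "gdm", "gestational diabetes (Carpenter-Coustan)")

  elsewhere <- if (has("delivered_elsewhere")) {
    isTRUE_v(cohort$delivered_elsewhere)
  } else {
    rep(FALSE, nrow(cohort))
  }
  cohort <- drop_stage(cohort, !elsewhere, "delivered_elsewhere",
    "delivered at another hospital")

  log <- dplyr::bind_rows(log)
  log$n_out <- log$n_in - log$n_excluded
  list(included = cohort, log = log)
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Cohort-flow bookkeeping from stage counts
#'
#' Telescopes published (or otherwise pre-tabulated) exclusion-stage counts
#' through the same cascade as [apply_exclusions()], without patient-level
#' data: total screened minus pre-screening exclusions gives the GCT pool,
#' removing unclassifiable / one-value / GDM gives the NGT pool, and
#' removing deliveries elsewhere gives the included cohort.
#'
#' @param n_total records reviewed.
#' @param n_pih excluded for hypertension before 24 GW.
#' @param n_no_weight excluded for missing weight record.
#' @param n_no_gct excluded for missing GCT.
#' @param n_no_ogtt GCT-positive without OGTT (unclassifiable).
#' @param n_one_value one-value abnormalities.
#' @param n_gdm GDM diagnoses.
#' @param n_elsewhere NGT women who delivered elsewhere.
#' @return a tibble log as in [apply_exclusions()], with attributes
#'   `n_screened` (GCT pool), `n_ngt` (NGT pool) and `n_included`.
#' @export
screening_flow_counts <- function(n_total, n_pih, n_no_weight, n_no_gct,
                                  n_no_ogtt, n_one_value, n_gdm,
                                  n_elsewhere) {
  stages <- tibble::tibble(
    stage = c(
      "pih", "no_weight_record", "no_gct", "no_ogtt",
      "one_value_abnormality", "gdm", "delivered_elsewhere"
    ),
    n_excluded = as.integer(c(
      n_pih, n_no_weight, n_no_gct, n_no_ogtt, n_one_value, n_gdm,
      n_elsewhere
    )),
    reason = c(
      "pregnancy-induced hypertension before 24 GW",
      "no maternal weight record", "no 50-g GCT result",
      "GCT-positive without OGTT (unclassifiable)",
      "one OGTT value at/above threshold",
      "gestational diabetes (Carpenter-Coustan)",
      "delivered at another hospital"
    )
  )
  n_in <- integer(nrow(stages))
  running <- as.integer(n_total)
  for (i in seq_len(nrow(stages))) {
    n_in[i] <- running
    running <- running - stages$n_excluded[i]
    if (running < 0) abort("stage counts exceed the running total.")
  }
  stages <- dplyr::mutate(stages,
    n_in = n_in, n_out = n_in - n_excluded,
    .before = "n_excluded"
  )
  structure(stages,
    n_screened = stages$n_out[stages$stage == "no_gct"],
    n_ngt = stages$n_out[stages$stage == "gdm"],
    n_included = running
  )
}

#' Assign maternal age-by-BMI subgroup
#'
#' Partition by the two clinical risk factors: advanced maternal age
#' (>= 35 years, inclusive) and pre-pregnancy obesity (BMI >= 25 kg/m^2,
#' inclusive). `G1` young/non-obese, `G2` young/obese, `G3` older/non-obese,
#' `G4` older/obese.
#'
#' @param age_years maternal age (vectorised).
#' @param prepreg_bmi pre-pregnancy BMI, kg/m^2.
#' @return factor with levels `G1`-`G4` (`NA` when either input is missing).
#' @export
assign_subgroup <- function(age_years, prepreg_bmi) {
  older <- age_years >= 35
  obese <- prepreg_bmi >= 25
  g <- dplyr::case_when(
    !older & !obese ~ "G1",
    !older & obese ~ "G2",
    older & !obese ~ "G3",
    older & obese ~ "G4"
  )
  factor(g, levels = c("G1", "G2", "G3", "G4"))
}

#' Homeostasis-model indices of insulin resistance and secretion
#'
#' HOMA1 closed forms from fasting glucose (mg/dL) and fasting insulin
#' (uU/mL):
#' \deqn{HOMA\mbox{-}IR = G \cdot I / 405, \qquad
#'       HOMA\mbox{-}\beta = 360 \cdot I / (G - 63).}
#' HOMA-beta is undefined at or below 63 mg/dL (singular denominator); it is
#' returned as `NA` there while HOMA-IR is still computed.
#'
#' @param fasting_glucose_mgdl fasting plasma glucose, mg/dL (> 0).
#' @param fasting_insulin_uUml fasting insulin, uU/mL (> 0).
#' @return tibble with columns `homa_ir`, `homa_beta`.
#' @examples
#' homa_indices(90, 7.2) # IR 1.6, beta 96
#' @export
homa_indices <- function(fasting_glucose_mgdl, fasting_insulin_uUml) {
  if (any(fasting_glucose_mgdl <= 0, na.rm = TRUE) ||
    any(fasting_insulin_uUml <= 0, na.rm = TRUE)) {
    abort("glucose and insulin must be positive.")
  }
  ir <- fasting_glucose_mgdl * fasting_insulin_uUml / 405
  beta <- ifelse(fasting_glucose_mgdl > 63,
    360 * fasting_insulin_uUml / (fasting_glucose_mgdl - 63),
    NA_real_
  )
  tibble::tibble(homa_ir = ir, homa_beta = beta)
}

#' Load a 90th-percentile birth-weight reference
#'
#' CSV with columns `ga_week` (completed gestational week at delivery),
#' `sex` (`male`/`female`) and `p90_g` (90th-percentile birth weight in
#' grams for that week and sex).
#'
#' @param path CSV path; `NULL` loads the shipped synthetic reference.
#' @return a validated tibble.
#' @export
load_lga_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lga_p90_synthetic.csv",
      package = "faor", mustWork = TRUE
    )
  }
  ref <- readr::read_csv(path, col_types = readr::cols(
    ga_week = readr::col_integer(),
    sex = readr::col_character(),
    p90_g = readr::col_double()
  ))
  if (!all(c("ga_week", "sex", "p90_g") %in% names(ref))) {
    abort("LGA reference needs columns ga_week, sex, p90_g.")
  }
  if (!all(ref$sex %in% c("male", "female"))) {
    abort("LGA reference `sex` must be 'male' or 'female'.")
  }
  if (any(ref$p90_g <= 0)) abort("p90_g must be positive.")
  ref
}

#' Label delivery outcomes: LGA and macrosomia
#'
#' Large-for-gestational-age (LGA) is a birth weight at or above the sex-
#' and gestational-week-matched 90th percentile of the reference table;
#' macrosomia is a birth weight at or above 4000 g (both inclusive). A
#' delivery week outside the reference leaves LGA missing while macrosomia
#' is still computed.
#'
#' @param birth_weight_g birth weight in grams (vectorised).
#' @param ga_delivery_days gestational age at delivery, days.
#' @param infant_sex `"male"`/`"female"`.
#' @param lga_reference a reference from [load_lga_reference()].
#' @param macrosomia_cutoff_g cutoff in grams (default 4000).
#' @return tibble with logical columns `lga`, `macrosomia`.
#' @export
label_outcomes <- function(birth_weight_g, ga_delivery_days, infant_sex,
                           lga_reference = load_lga_reference(),
                           macrosomia_cutoff_g = 4000) {
  week <- floor(ga_delivery_days / 7)
  key <- paste(week, infant_sex)
  ref_key <- paste(lga_reference$ga_week, lga_reference$sex)
  p90 <- lga_reference$p90_g[match(key, ref_key)]
  tibble::tibble(
    lga = ifelse(is.na(p90) | is.na(birth_weight_g), NA,
      birth_weight_g >= p90
    ),
    macrosomia = birth_weight_g >= macrosomia_cutoff_g
  )
}
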