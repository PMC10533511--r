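# End-to-end study pipeline: exclusion cascade -> glycemic classification
# -> subgrouping -> gestational-age estimation -> overgrowth ratios and FAO
# classification -> delivery-outcome labels -> statistical tables.

#' Prepare the per-record analysis table
#'
#' Runs the record-level stages in study order -- exclusion cascade,
#' glycemic classification, subgroup assignment, gestational-age estimation
#' by chart inversion, overgrowth ratios, FAOR cutoff derivation and FAO
#' classification (mid-gestation and near term), estimated fetal weight,
#' homeostasis-model indices and delivery-outcome labels -- and returns the
#' annotated included cohort together with the exclusion log and the
#' cutoffs in force. [run_study()] builds its tables from this; it is
#' exported so custom models can be fitted on the same analysis set.
#'
#' @param cohort a cohort tibble or path to a cohort CSV.
#' @param config a [faor_config()].
#' @return list with `data` (annotated tibble: derived covariates,
#'   `subgroup`, per-ratio gestational ages, `faor_*`, `fao_*` flags,
#'   `efw_g`, `homa_*`, outcome labels), `exclusion_log`, `thresholds`,
#'   `thresholds_near` and `n_input`.
#' @export
prepare_study_data <- function(cohort, config = faor_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  n_input <- nrow(cohort)
  excl <- apply_exclusions(cohort, config)
  d <- annotate_cohort(excl$included, config)

  if (nrow(d) == 0) {
    return(list(
      data = d, exclusion_log = excl$log, thresholds = NULL,
      thresholds_near = NULL, n_input = n_input
    ))
  }

  bio <- d[d$has_biometry_mid, , drop = FALSE]
  thresholds <- if (config$fao$use_fixed || sum(is.finite(bio$faor_lmp)) < 10) {
    default_fao_thresholds(config)
  } else {
    empirical_thresholds(
      bio[, c("faor_lmp", "faor_bpd", "faor_fl")],
      level = config$fao$level
    )
  }
  headline <- config$fao$headline
  flags_mid <- classify_fao(
    tibble::tibble(
      faor_lmp = d$faor_lmp, faor_bpd = d$faor_bpd, faor_fl = d$faor_fl
    ),
    thresholds, headline
  )
  d$fao_lmp <- flags_mid$fao_lmp
  d$fao_bpd <- flags_mid$fao_bpd
  d$fao_fl <- flags_mid$fao_fl
  d$fao_mid <- flags_mid$fao_headline

  thresholds_near <- if (isTRUE(config$fao$rederive_near)) {
    near <- d[!is.na(d$faor_near_lmp), , drop = FALSE]
    if (sum(is.finite(near$faor_near_lmp)) >= 10) {
      empirical_thresholds(
        tibble::tibble(
          faor_lmp = near$faor_near_lmp, faor_bpd = near$faor_near_bpd,
          faor_fl = near$faor_near_fl
        ),
        level = config$fao$level
      )
    } else {
      thresholds
    }
  } else {
    thresholds
  }
  d$fao_near <- classify_fao(
    tibble::tibble(
      faor_lmp = d$faor_near_lmp, faor_bpd = d$faor_near_bpd,
      faor_fl = d$faor_near_fl
    ),
    thresholds_near, headline
  )$fao_headline

  list(
    data = d, exclusion_log = excl$log, thresholds = thresholds,
    thresholds_near = thresholds_near, n_input = n_input
  )
}

#' Run the full cohort analysis
#'
#' Executes [prepare_study_data()] and then the statistical battery,
#' returning an `faor_report` holding the rendered-table inputs (per-cell
#' numerators and denominators, never bare percentages), the exclusion log,
#' the derived FAOR cutoffs and an echo of the configuration. The run is
#' deterministic: no randomness is used after the cohort is fixed.
#'
#' @param cohort a cohort tibble or a path to a cohort CSV
#'   (see [read_cohort()] for the schema).
#' @param config a [faor_config()].
#' @return an object of class `faor_report`.
#' @export
run_study <- function(cohort, config = faor_config()) {
  prep <- prepare_study_data(cohort, config)
  d <- prep$data

  report <- list(
    n_input = prep$n_input,
    n_included = nrow(d),
    exclusion_log = prep$exclusion_log,
    config_echo = unclass(config),
    adjust_set = config$adjust$covariates
  )

  if (nrow(d) == 0) {
    report <- c(report, list(
      thresholds = NULL, table1 = NULL, table2 = NULL, table3 = NULL,
      table4 = NULL, table5 = NULL, table6 = NULL
    ))
    return(structure(report, class = "faor_report"))
  }

  thresholds <- prep$thresholds
  fam <- config$pairwise_family

  table1 <- summarise_by_group(d, c(
    "age_years", "prepreg_bmi", "weight_gain_dx", "weight_gain_term",
    "gct_mgdl", "ogtt_fasting_mgdl", "hba1c_pct", "homa_ir", "homa_beta"
  ), family_size = fam)

  bio <- d[d$has_biometry_mid, , drop = FALSE]
  table2 <- summarise_by_group(bio, c(
    "ga_lmp_mid_wk", "ga_ac_mid_wk", "ga_bpd_mid_wk", "ga_fl_mid_wk",
    "efw_g", "faor_lmp", "faor_bpd", "faor_fl"
  ), family_size = fam)

  table3 <- list(
    cells = dplyr::bind_rows(
      prevalence_by_group(bio, "fao_mid", "FAO at diagnosis", fam),
      prevalence_by_group(d, "primipara", "Primipara", fam),
      prevalence_by_group(d, "cesarean", "Cesarean delivery", fam),
      prevalence_by_group(d, "primary_cesarean", "Primary cesarean delivery", fam),
      prevalence_by_group(d, "lga", "LGA", fam),
      prevalence_by_group(d, "macrosomia", "Macrosomia", fam)
    ),
    continuous = summarise_by_group(
      d, c("birth_weight_g", "ga_delivery_wk"),
      family_size = fam
    )
  )

  covars <- config$adjust$covariates
  group_excl <- c("age_years", "prepreg_bmi") # exposure-defining variables
  table4 <- dplyr::bind_rows(lapply(
    c(lmp = "fao_lmp", bpd = "fao_bpd", fl = "fao_fl"),
    function(col) {
      fit_or_safe(bio, col, covars, group_excl)
    }
  ), .id = "criterion")

  table5 <- dplyr::bind_rows(lapply(
    c(
      lga = "lga", macrosomia = "macrosomia",
      primary_cesarean = "primary_cesarean"
    ),
    function(col) fit_or_safe(d, col, covars, group_excl)
  ), .id = "outcome")

  table6 <- compare_by_fao(bio)

  report <- c(report, list(
    n_biometry = nrow(bio),
    thresholds = thresholds,
    thresholds_near = prep$thresholds_near,
    table1 = table1, table2 = table2, table3 = table3,
    table4 = table4, table5 = table5, table6 = table6
  ))
  structure(report, class = "faor_report")
}

# Derived per-record variables shared by all tables.
annotate_cohort <- function(d, config) {
  charts <- resolve_charts(config)
  d$prepreg_bmi <- d$prepreg_weight_kg / d$height_m^2
  d$weight_gain_dx <- d$weight_at_dx_kg - d$prepreg_weight_kg
  d$weight_gain_term <- d$weight_near_term_kg - d$prepreg_weight_kg
  d$subgroup <- assign_subgroup(d$age_years, d$prepreg_bmi)

  est <- function(chart, mm) estimate_ga(chart, mm, out_of_range = "na")
  d$ga_ac_mid <- est(charts$ac, d$ac_mid_mm)
  d$ga_bpd_mid <- est(charts$bpd, d$bpd_mid_mm)
  d$ga_fl_mid <- est(charts$fl, d$fl_mid_mm)
  d$ga_ac_near <- est(charts$ac, d$ac_near_mm)
  d$ga_bpd_near <- est(charts$bpd, d$bpd_near_mm)
  d$ga_fl_near <- est(charts$fl, d$fl_near_mm)
  d$has_biometry_mid <- !is.na(d$ga_ac_mid) & !is.na(d$ga_bpd_mid) &
    !is.na(d$ga_fl_mid) & !is.na(d$ga_lmp_mid_days)

  fa_mid <- compute_faors(d$ga_ac_mid, d$ga_lmp_mid_days, d$ga_bpd_mid, d$ga_fl_mid)
  d$faor_lmp <- fa_mid$faor_lmp
  d$faor_bpd <- fa_mid$faor_bpd
  d$faor_fl <- fa_mid$faor_fl
  fa_near <- compute_faors(d$ga_ac_near, d$ga_lmp_near_days, d$ga_bpd_near, d$ga_fl_near)
  d$faor_near_lmp <- fa_near$faor_lmp
  d$faor_near_bpd <- fa_near$faor_bpd
  d$faor_near_fl <- fa_near$faor_fl

  d$efw_g <- estimate_fetal_weight(
    d$bpd_mid_mm / 10, d$ac_mid_mm / 10, d$fl_mid_mm / 10,
    coef_bpd3 = config$efw$coef_bpd3, coef_ac2fl = config$efw$coef_ac2fl
  )
  d$ga_lmp_mid_wk <- d$ga_lmp_mid_days / 7
  d$ga_ac_mid_wk <- d$ga_ac_mid / 7
  d$ga_bpd_mid_wk <- d$ga_bpd_mid / 7
  d$ga_fl_mid_wk <- d$ga_fl_mid / 7
  d$ga_delivery_wk <- d$ga_delivery_days / 7

  hb <- homa_indices(
    pmax(d$ogtt_fasting_mgdl, 1e-9), pmax(d$fasting_insulin_uUml, 1e-9)
  )
  have_homa <- !is.na(d$ogtt_fasting_mgdl) & !is.na(d$fasting_insulin_uUml)
  d$homa_ir <- ifelse(have_homa, hb$homa_ir, NA_real_)
  d$homa_beta <- ifelse(have_homa, hb$homa_beta, NA_real_)

  ref <- if (is.null(config$lga$reference_path)) {
    load_lga_reference()
  } else {
    load_lga_reference(config$lga$reference_path)
  }
  lab <- label_outcomes(
    d$birth_weight_g, d$ga_delivery_days, d$infant_sex,
    lga_reference = ref, macrosomia_cutoff_g = config$macrosomia$cutoff_g
  )
  d$lga <- lab$lga
  d$macrosomia <- lab$macrosomia
  d$primipara <- d$parity == "primipara"
  d$male <- d$infant_sex == "male"
  d$cesarean <- d$delivery_mode %in% c("primary_cesarean", "repeat_cesarean")
  d$primary_cesarean <- d$delivery_mode == "primary_cesarean"
  d
}

group_levels <- c("G1", "G2", "G3", "G4")

# mean +/- sd per group and total, with pairwise Welch t tests.
summarise_by_group <- function(d, vars, family_size) {
  summary <- dplyr::bind_rows(lapply(vars, function(v) {
    per_group <- lapply(c("Total", group_levels), function(g) {
      x <- if (g == "Total") d[[v]] else d[[v]][d$subgroup == g]
      x <- x[!is.na(x)]
      tibble::tibble(
        variable = v, group = g, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) sd(x) else NA_real_
      )
    })
    dplyr::bind_rows(per_group)
  }))
  pairs <- utils::combn(group_levels, 2)
  pairwise <- dplyr::bind_rows(lapply(vars, function(v) {
    dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
      ga <- pairs[1, j]
      gb <- pairs[2, j]
      x <- d[[v]][d$subgroup == ga]
      y <- d[[v]][d$subgroup == gb]
      res <- tryCatch(
        two_sample_t(x, y, family_size = family_size),
        error = function(e) NULL
      )
      if (is.null(res)) {
        return(tibble::tibble(
          variable = v, group_a = ga, group_b = gb,
          estimate = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_
        ))
      }
      tibble::tibble(
        variable = v, group_a = ga, group_b = gb,
        estimate = res$estimate, p_raw = res$p_raw,
        p_adjusted = res$p_adjusted
      )
    }))
  }))
  list(summary = summary, pairwise = pairwise)
}

#' Prevalence cell with explicit denominator
#'
#' @param k numerator (events).
#' @param n denominator.
#' @return one-row tibble `k`, `n`, `pct` where `pct` is the half-up
#'   one-decimal percentage; `NA` percentage for an empty denominator.
#' @export
prevalence_cell <- function(k, n) {
  tibble::tibble(
    k = as.integer(k), n = as.integer(n),
    pct = if (n > 0) round_half_up(100 * k / n, 1) else NA_real_
  )
}

prevalence_by_group <- function(d, col, label, family_size) {
  cells <- dplyr::bind_rows(lapply(c("Total", group_levels), function(g) {
    x <- if (g == "Total") d[[col]] else d[[col]][d$subgroup == g]
    x <- x[!is.na(x)]
    dplyr::mutate(prevalence_cell(sum(x), length(x)),
      variable = label, group = g, .before = 1
    )
  }))
  pairs <- utils::combn(group_levels, 2)
  pairwise <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1, j]
    gb <- pairs[2, j]
    ca <- cells[cells$group == ga, ]
    cb <- cells[cells$group == gb, ]
    if (ca$n == 0 || cb$n == 0) {
      return(tibble::tibble(
        variable = label, group_a = ga, group_b = gb,
        estimate = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_
      ))
    }
    res <- proportion_test(ca$k, ca$n, cb$k, cb$n, family_size = family_size)
    tibble::tibble(
      variable = label, group_a = ga, group_b = gb,
      estimate = res$estimate, p_raw = res$p_raw, p_adjusted = res$p_adjusted
    )
  }))
  attr(cells, "pairwise") <- pairwise
  cells
}

fit_or_safe <- function(d, outcome, covariates, exclude) {
  tryCatch(
    fit_logistic_or(
      d,
      outcome = outcome, exposure = "subgroup",
      covariates = covariates, reference = "G1",
      exclude_covariates = exclude
    ),
    error = function(e) {
      tibble::tibble(
        level = character(), estimate = numeric(), ci_low = numeric(),
        ci_high = numeric(), p_raw = numeric(), n_used = integer(),
        separation = logical()
      )
    }
  )
}

# FAO-present vs FAO-absent comparison on the biometry subset.
compare_by_fao <- function(bio) {
  yes <- bio[isTRUE_v(bio$fao_mid), , drop = FALSE]
  no <- bio[isTRUE_v(!bio$fao_mid), , drop = FALSE]
  cont_vars <- c(
    "age_years", "prepreg_bmi", "weight_gain_dx", "weight_gain_term",
    "hba1c_pct", "gct_mgdl", "ogtt_fasting_mgdl", "homa_ir", "homa_beta"
  )
  continuous <- dplyr::bind_rows(lapply(cont_vars, function(v) {
    x <- no[[v]][!is.na(no[[v]])]
    y <- yes[[v]][!is.na(yes[[v]])]
    p <- tryCatch(two_sample_t(y, x)$p_raw, error = function(e) NA_real_)
    tibble::tibble(
      variable = v,
      n_absent = length(x), mean_absent = mean(x), sd_absent = sd(x),
      n_present = length(y), mean_present = mean(y), sd_present = sd(y),
      p_raw = p
    )
  }))
  cat_vars <- c(
    fao_near = "FAO (+) near term", primipara = "Primipara",
    male = "Male sex of infant", lga = "LGA at birth",
    macrosomia = "Macrosomia", primary_cesarean = "Primary cesarean delivery"
  )
  categorical <- dplyr::bind_rows(lapply(names(cat_vars), function(v) {
    x <- no[[v]][!is.na(no[[v]])]
    y <- yes[[v]][!is.na(yes[[v]])]
    p <- if (length(x) && length(y)) {
      proportion_test(sum(y), length(y), sum(x), length(x))$p_raw
    } else {
      NA_real_
    }
    ca <- prevalence_cell(sum(x), length(x))
    cy <- prevalence_cell(sum(y), length(y))
    tibble::tibble(
      variable = cat_vars[[v]],
      k_absent = ca$k, n_absent = ca$n, pct_absent = ca$pct,
      k_present = cy$k, n_present = cy$n, pct_present = cy$pct,
      p_raw = p
    )
  }))
  list(
    n_absent = nrow(no), n_present = nrow(yes),
    continuous = continuous, categorical = categorical
  )
}
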