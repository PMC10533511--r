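# Analysis configuration: screening thresholds, FAO classification options,
# EFW coefficients, chart paths and the adjustment set for model-based odds
# ratios. All values can be overridden from a YAML file or by argument.

#' Default analysis configuration
#'
#' Returns the full configuration list used by [run_study()] and the
#' lower-level functions, optionally merged with overrides from a YAML file
#' and/or a named list. Keys (YAML paths in dots):
#'
#' * `gct.threshold` -- 50-g glucose challenge screen-positive cutoff,
#'   mg/dL (default 140, inclusive).
#' * `cc.fasting`, `cc.h1`, `cc.h2`, `cc.h3` -- Carpenter-Coustan 100-g OGTT
#'   thresholds, mg/dL (defaults 95/180/155/140, inclusive); two or more
#'   exceedances diagnose GDM, exactly one is a one-value abnormality.
#' * `macrosomia.cutoff_g` -- birth-weight cutoff for macrosomia (4000).
#' * `efw.coef_bpd3`, `efw.coef_ac2fl` -- EFW polynomial coefficients.
#' * `chart.path.bpd|ac|fl` -- growth-chart CSV paths (`NULL` = shipped
#'   synthetic charts).
#' * `fao.level` -- percentile level for FAOR cutoffs (0.90).
#' * `fao.headline` -- which criterion defines the single headline FAO flag:
#'   `"lmp"` (default), `"bpd"`, `"fl"` or `"union"`.
#' * `fao.use_fixed` -- classify with `fao.fixed_cutoffs` instead of
#'   deriving cutoffs from the analysed cohort.
#' * `fao.fixed_cutoffs` -- published-style fixed cutoffs
#'   (1.080/1.071/1.069) for classifying external records.
#' * `fao.rederive_near` -- re-derive cutoffs from near-term ratios rather
#'   than carrying over the mid-gestation cutoffs.
#' * `adjust.covariates` -- covariates for adjusted odds ratios; variables
#'   that define the exposure are removed automatically.
#'
#' @param path optional YAML file with overrides.
#' @param overrides optional named list with overrides (applied last).
#' @return a nested configuration list of class `faor_config`.
#' @export
faor_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    gct = list(threshold = 140),
    cc = list(fasting = 95, h1 = 180, h2 = 155, h3 = 140),
    macrosomia = list(cutoff_g = 4000),
    efw = list(coef_bpd3 = 1.07, coef_ac2fl = 0.30),
    chart = list(path = list(bpd = NULL, ac = NULL, fl = NULL)),
    lga = list(reference_path = NULL),
    fao = list(
      level = 0.90,
      headline = "lmp",
      use_fixed = FALSE,
      fixed_cutoffs = list(lmp = 1.080, bpd = 1.071, fl = 1.069),
      rederive_near = FALSE
    ),
    adjust = list(
      covariates = c("age_years", "prepreg_bmi", "weight_gain_dx", "gct_mgdl")
    ),
    alpha = 0.05,
    pairwise_family = 6
  )
  if (!is.null(path)) {
    cfg <- modify_list_deep(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) {
    cfg <- modify_list_deep(cfg, overrides)
  }
  structure(cfg, class = c("faor_config", "list"))
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

# Resolve the three charts named in the config (NULL -> shipped defaults).
resolve_charts <- function(config) {
  lapply(setNames(CHART_KINDS, CHART_KINDS), function(kind) {
    p <- config$chart$path[[kind]]
    if (is.null(p)) default_growth_chart(kind) else load_growth_chart(p, kind)
  })
}
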