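# Fetal abdominal overgrowth ratios (FAORs) and FAO classification.
#
# Each ratio compares the ultrasound-estimated gestational age of the
# abdominal circumference (GA-AC) with a denominator gestational age:
# GA-LMP (actual, by dates) corrects for scan-timing variation, GA-BPD and
# GA-FL detect overgrowth of the abdomen relative to head and femur.
# Fetal abdominal obesity (FAO) is a ratio at or above the cohort's
# empirical 90th percentile.

#' Compute fetal abdominal overgrowth ratios
#'
#' @param ga_ac estimated gestational age by abdominal circumference.
#' @param ga_lmp actual gestational age by last menstrual period.
#' @param ga_bpd estimated gestational age by biparietal diameter.
#' @param ga_fl estimated gestational age by femur length.
#'
#' All four on the same scale (days or decimal weeks); the ratios are
#' unit-invariant, i.e. unchanged under any common rescaling of the four
#' gestational ages.
#'
#' @return tibble with columns `faor_lmp` (GA-AC/GA-LMP), `faor_bpd`
#'   (GA-AC/GA-BPD), `faor_fl` (GA-AC/GA-FL); `NA` where an input is
#'   missing.
#' @export
compute_faors <- function(ga_ac, ga_lmp, ga_bpd, ga_fl) {
  for (v in list(ga_ac, ga_lmp, ga_bpd, ga_fl)) {
    if (any(v <= 0, na.rm = TRUE)) {
      abort("gestational ages must be positive to form FAORs.")
    }
  }
  tibble::tibble(
    faor_lmp = ga_ac / ga_lmp,
    faor_bpd = ga_ac / ga_bpd,
    faor_fl = ga_ac / ga_fl
  )
}

#' Empirical FAOR cutoffs from a reference cohort
#'
#' Derives the per-ratio cutoff as the empirical quantile (default level
#' 0.90) of the reference cohort's ratios, using linear interpolation
#' between order statistics (the type-7 convention). Non-finite ratios are
#' dropped and counted; at least 10 finite values per ratio are required.
#'
#' @param faors tibble from [compute_faors()] (columns `faor_lmp`,
#'   `faor_bpd`, `faor_fl`).
#' @param level quantile level in (0, 1), default 0.90.
#' @return an object of class `fao_thresholds`: list with `level`,
#'   `cut_lmp`, `cut_bpd`, `cut_fl`, `n_reference` and `n_dropped`.
#' @export
empirical_thresholds <- function(faors, level = 0.90) {
  stopifnot_scalar_number(level, "level")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  cols <- c("faor_lmp", "faor_bpd", "faor_fl")
  if (!all(cols %in% names(faors))) {
    abort("`faors` must have columns faor_lmp, faor_bpd, faor_fl.")
  }
  cuts <- numeric(3)
  n_ref <- integer(3)
  n_drop <- integer(3)
  for (i in seq_along(cols)) {
    v <- faors[[cols[i]]]
    fin <- v[is.finite(v)]
    n_drop[i] <- length(v) - length(fin)
    if (length(fin) < 10L) {
      abort(sprintf(
        "need at least 10 finite values of %s to derive a cutoff (got %d).",
        cols[i], length(fin)
      ))
    }
    cuts[i] <- unname(quantile(fin, probs = level, type = 7))
    n_ref[i] <- length(fin)
  }
  fao_thresholds(
    cut_lmp = cuts[1], cut_bpd = cuts[2], cut_fl = cuts[3],
    level = level, n_reference = n_ref,
    n_dropped = setNames(n_drop, cols)
  )
}

#' Construct a FAOR cutoff set
#'
#' Mostly called through [empirical_thresholds()]; the direct constructor
#' exists so that externally published cutoffs can be used to classify
#' records without a reference cohort (see [default_fao_thresholds()]).
#'
#' @param cut_lmp,cut_bpd,cut_fl positive cutoff values for the three
#'   ratios.
#' @param level the percentile level the cutoffs represent.
#' @param n_reference size of the reference cohort per ratio (`NA` for
#'   external cutoffs).
#' @param n_dropped non-finite values dropped per ratio.
#' @return an object of class `fao_thresholds`.
#' @export
fao_thresholds <- function(cut_lmp, cut_bpd, cut_fl, level = 0.90,
                           n_reference = NA_integer_,
                           n_dropped = c(faor_lmp = 0L, faor_bpd = 0L, faor_fl = 0L)) {
  if (any(c(cut_lmp, cut_bpd, cut_fl) <= 0)) {
    abort("cutoffs must be positive.")
  }
  structure(
    list(
      level = level, cut_lmp = cut_lmp, cut_bpd = cut_bpd, cut_fl = cut_fl,
      n_reference = n_reference, n_dropped = n_dropped
    ),
    class = "fao_thresholds"
  )
}

#' @export
print.fao_thresholds <- function(x, ...) {
  cat(sprintf(
    "<fao_thresholds: level %.2f | GA-AC/GA-LMP >= %.4f, GA-AC/GA-BPD >= %.4f, GA-AC/GA-FL >= %.4f | n_ref %s>\n",
    x$level, x$cut_lmp, x$cut_bpd, x$cut_fl,
    paste(x$n_reference, collapse = "/")
  ))
  invisible(x)
}

#' Fixed reference cutoffs shipped with the package
#'
#' The 90th-percentile cutoffs 1.080 (GA-AC/GA-LMP), 1.071 (GA-AC/GA-BPD)
#' and 1.069 (GA-AC/GA-FL), for classifying external records when no
#' reference cohort is available.
#'
#' @param config a [faor_config()]; reads `fao.fixed_cutoffs` and
#'   `fao.level`.
#' @return an `fao_thresholds` object.
#' @export
default_fao_thresholds <- function(config = faor_config()) {
  fc <- config$fao$fixed_cutoffs
  fao_thresholds(fc$lmp, fc$bpd, fc$fl, level = config$fao$level)
}

#' Classify fetal abdominal obesity
#'
#' Flags each ratio at or above its cutoff (inclusive), and a single
#' headline flag used for prevalence and outcome analyses. The headline
#' criterion defaults to the GA-AC/GA-LMP ratio and can be set to any
#' single ratio or to the union of the three.
#'
#' @param faors tibble from [compute_faors()].
#' @param thresholds an `fao_thresholds` object.
#' @param headline `"lmp"` (default), `"bpd"`, `"fl"` or `"union"`.
#' @return tibble with logical columns `fao_lmp`, `fao_bpd`, `fao_fl`,
#'   `fao_headline`.
#' @export
classify_fao <- function(faors, thresholds, headline = c("lmp", "bpd", "fl", "union")) {
  stopifnot(inherits(thresholds, "fao_thresholds"))
  headline <- match.arg(headline)
  flags <- tibble::tibble(
    fao_lmp = faors$faor_lmp >= thresholds$cut_lmp,
    fao_bpd = faors$faor_bpd >= thresholds$cut_bpd,
    fao_fl = faors$faor_fl >= thresholds$cut_fl
  )
  flags$fao_headline <- switch(headline,
    lmp = flags$fao_lmp,
    bpd = flags$fao_bpd,
    fl = flags$fao_fl,
    union = flags$fao_lmp | flags$fao_bpd | flags$fao_fl
  )
  flags
}
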