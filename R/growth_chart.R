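# Growth-chart reference curves: forward evaluation (gestational age ->
# median biometry) and inversion (measured biometry -> ultrasound-estimated
# gestational age). Charts are pluggable CSV tables so that any published
# reference (or a synthetic one) can be swapped in.

CHART_KINDS <- c("bpd", "ac", "fl")

#' Construct a growth-chart table
#'
#' A growth chart maps gestational age (days since the last menstrual
#' period, LMP) to the population-median value of one fetal biometry
#' measurement: biparietal diameter (BPD), abdominal circumference (AC) or
#' femur length (FL). Fetal dimensions grow monotonically over the second
#' and third trimester, so both columns must be strictly increasing; this is
#' what makes the chart invertible and GA estimation from a measurement
#' well defined.
#'
#' @param ga_days integer-valued gestational ages in days, strictly
#'   increasing.
#' @param median_mm median measurement in millimetres at each `ga_days`,
#'   strictly increasing.
#' @param kind one of `"bpd"`, `"ac"`, `"fl"`.
#' @return an object of class `growth_chart` with a `valid_range` attribute
#'   (the first and last `ga_days`).
#' @seealso [load_growth_chart()], [expected_biometry()], [estimate_ga()]
#' @export
growth_chart <- function(ga_days, median_mm, kind) {
  kind <- match.arg(tolower(kind), CHART_KINDS)
  ga_days <- as.numeric(ga_days)
  median_mm <- as.numeric(median_mm)
  if (length(ga_days) != length(median_mm)) {
    abort("`ga_days` and `median_mm` must have the same length.")
  }
  if (length(ga_days) < 2L) {
    abort("a growth chart needs at least two rows.")
  }
  if (anyNA(ga_days) || anyNA(median_mm)) {
    abort("growth-chart tables must not contain missing values.")
  }
  if (anyDuplicated(ga_days)) {
    abort("duplicate `ga_days` in growth chart.")
  }
  if (any(diff(ga_days) <= 0)) {
    abort("`ga_days` must be strictly increasing.")
  }
  if (any(diff(median_mm) <= 0)) {
    abort(sprintf(
      "`median_mm` must be strictly increasing for a %s chart (fetal dimensions grow monotonically).",
      toupper(kind)
    ))
  }
  if (any(median_mm <= 0)) {
    abort("`median_mm` must be positive.")
  }
  structure(
    list(kind = kind, ga_days = ga_days, median_mm = median_mm),
    valid_range = c(ga_days[1L], ga_days[length(ga_days)]),
    class = "growth_chart"
  )
}

#' @export
print.growth_chart <- function(x, ...) {
  vr <- attr(x, "valid_range")
  cat(sprintf(
    "<growth_chart: %s, %d knots, GA %.0f-%.0f days (%.1f-%.1f wk), median %.1f-%.1f mm>\n",
    toupper(x$kind), length(x$ga_days), vr[1], vr[2], vr[1] / 7, vr[2] / 7,
    x$median_mm[1], x$median_mm[length(x$median_mm)]
  ))
  invisible(x)
}

#' Load a growth chart from CSV
#'
#' Reads a two-column table `ga_days,median_mm` (header required, UTF-8) and
#' validates it as a [growth_chart()]. Non-monotone or duplicated rows are
#' rejected rather than repaired.
#'
#' @param path path to the CSV file.
#' @param kind measurement kind, `"bpd"`, `"ac"` or `"fl"`.
#' @return a `growth_chart` object.
#' @export
load_growth_chart <- function(path, kind) {
  if (!file.exists(path)) {
    abort(sprintf("growth-chart file not found: %s", path))
  }
  tab <- readr::read_csv(path, col_types = readr::cols(
    ga_days = readr::col_double(),
    median_mm = readr::col_double()
  ))
  if (!all(c("ga_days", "median_mm") %in% names(tab))) {
    abort("growth-chart CSV must have columns `ga_days` and `median_mm`.")
  }
  growth_chart(tab$ga_days, tab$median_mm, kind)
}

#' Default growth charts shipped with the package
#'
#' Returns the synthetic reference chart for one measurement, built from a
#' smooth monotone curve tabulated at weekly knots from 14 to 43 weeks.
#' These charts are stand-ins for a published national reference (which is a
#' site-specific choice); they are labelled synthetic and every analysis in
#' the package is chart-agnostic, relying only on monotonicity.
#'
#' @param kind `"bpd"`, `"ac"` or `"fl"`.
#' @return a `growth_chart`.
#' @export
default_growth_chart <- function(kind) {
  kind <- match.arg(tolower(kind), CHART_KINDS)
  path <- system.file("extdata", sprintf("chart_%s_synthetic.csv", kind),
    package = "faor", mustWork = FALSE
  )
  if (nzchar(path) && file.exists(path)) {
    return(load_growth_chart(path, kind))
  }
  # Fall back to building the same table in code (e.g. before installation).
  ga_days <- seq(14L * 7L, 43L * 7L, by = 7L)
  growth_chart(ga_days, biometry_curve(kind, ga_days), kind)
}

#' Smooth forward biometry curves
#'
#' The monotone quadratic curves (in gestational weeks) from which the
#' shipped synthetic charts are tabulated. Values are in millimetres and in
#' the physiological range of mid/late-gestation fetal biometry; their role
#' is to provide a realistic, strictly increasing forward model, not to
#' reproduce any published national chart.
#'
#' @param kind `"bpd"`, `"ac"` or `"fl"`.
#' @param ga_days gestational age in days.
#' @return median measurement in mm.
#' @export
biometry_curve <- function(kind, ga_days) {
  kind <- match.arg(tolower(kind), CHART_KINDS)
  w <- ga_days / 7
  switch(kind,
    bpd = -33 + 4.9 * w - 0.040 * w^2,
    ac  = -45 + 9.2 * w + 0.005 * w^2,
    fl  = -21 + 2.5 * w - 0.0015 * w^2
  )
}

#' Median biometry expected at a gestational age
#'
#' Forward evaluation of a growth chart: the chart's knots are interpolated
#' linearly, which preserves strict monotonicity and is exact at the knots.
#'
#' @param chart a [growth_chart()].
#' @param ga_days gestational age in days (vectorised); must lie inside the
#'   chart's valid range.
#' @return expected median measurement in mm.
#' @export
expected_biometry <- function(chart, ga_days) {
  stopifnot(inherits(chart, "growth_chart"))
  vr <- attr(chart, "valid_range")
  bad <- !is.na(ga_days) & (ga_days < vr[1] | ga_days > vr[2])
  if (any(bad)) {
    abort(sprintf(
      "gestational age outside chart valid range [%.0f, %.0f] days.",
      vr[1], vr[2]
    ))
  }
  approx(chart$ga_days, chart$median_mm, xout = ga_days, ties = "ordered")$y
}

#' Estimate gestational age from a biometry measurement
#'
#' Inverts the chart: finds the unique gestational age at which the chart's
#' median equals the measured value. Because charts are tabulated (not
#' analytic), the inverse is found by bisection on the piecewise-linear
#' monotone interpolant, to a tolerance of 1e-3 day -- far below clinical
#' resolution.
#'
#' Measurements outside the chart's value range cannot be converted; they are
#' either raised as an error (default) or returned as `NA` so that the
#' calling pipeline can flag and log the record instead of dropping it
#' silently.
#'
#' @param chart a [growth_chart()].
#' @param measurement_mm measured value in mm (vectorised).
#' @param out_of_range `"error"` or `"na"`.
#' @param tol bisection tolerance in days.
#' @return estimated gestational age in days.
#' @export
estimate_ga <- function(chart, measurement_mm, out_of_range = c("error", "na"),
                        tol = 1e-3) {
  stopifnot(inherits(chart, "growth_chart"))
  out_of_range <- match.arg(out_of_range)
  m <- as.numeric(measurement_mm)
  lo_val <- chart$median_mm[1L]
  hi_val <- chart$median_mm[length(chart$median_mm)]
  out <- rep(NA_real_, length(m))
  oob <- !is.na(m) & (m < lo_val | m > hi_val)
  if (any(oob) && out_of_range == "error") {
    abort(sprintf(
      "measurement outside chart value range [%.1f, %.1f] mm; record should be flagged as unconvertible.",
      lo_val, hi_val
    ))
  }
  ok <- !is.na(m) & !oob
  if (!any(ok)) {
    return(out)
  }
  vr <- attr(chart, "valid_range")
  lo <- rep(vr[1], sum(ok))
  hi <- rep(vr[2], sum(ok))
  target <- m[ok]
  n_iter <- ceiling(log2((vr[2] - vr[1]) / tol)) + 1L
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    f <- approx(chart$ga_days, chart$median_mm, xout = mid, ties = "ordered")$y
    below <- f < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out[ok] <- (lo + hi) / 2
  out
}

#' Estimated fetal weight from biometry
#'
#' Computes EFW (grams) from biparietal diameter, abdominal circumference
#' and femur length in centimetres with the standard Japanese-ultrasound
#' polynomial form
#' \deqn{EFW = c_1 \cdot BPD^3 + c_2 \cdot AC^2 \cdot FL,}
#' with default coefficients \eqn{c_1 = 1.07} and \eqn{c_2 = 0.30}. Both
#' coefficients are configurable so an alternative EFW formula of the same
#' form can be substituted.
#'
#' @param bpd_cm,ac_cm,fl_cm biometry in cm, all non-negative (vectorised).
#' @param coef_bpd3 coefficient on `bpd_cm^3`.
#' @param coef_ac2fl coefficient on `ac_cm^2 * fl_cm`.
#' @return estimated fetal weight in grams.
#' @examples
#' estimate_fetal_weight(6.5, 21.5, 4.7) # 945.62 g
#' @export
estimate_fetal_weight <- function(bpd_cm, ac_cm, fl_cm,
                                  coef_bpd3 = 1.07, coef_ac2fl = 0.30) {
  if (any(bpd_cm < 0, na.rm = TRUE) || any(ac_cm < 0, na.rm = TRUE) ||
    any(fl_cm < 0, na.rm = TRUE)) {
    abort("biometry inputs to EFW must be non-negative.")
  }
  coef_bpd3 * bpd_cm^3 + coef_ac2fl * ac_cm^2 * fl_cm
}
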