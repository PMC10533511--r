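# The statistical battery behind the cohort tables: pairwise two-sample
# t tests and proportion tests with Bonferroni correction, crude odds
# ratios from 2x2 tables, model-based odds ratios from logistic fits,
# Pearson correlations and multiple linear regression of the overgrowth
# ratios on clinical factors. All comparisons are two-sided at alpha 0.05.

comparison_result <- function(estimate, ci_low, ci_high, p_raw, method,
                              family_size = 1L, ...) {
  tibble::tibble(
    estimate = estimate, ci_low = ci_low, ci_high = ci_high,
    p_raw = p_raw,
    p_adjusted = bonferroni_adjust(p_raw, family_size),
    family_size = as.integer(family_size),
    method = method,
    ...
  )
}

#' Two-sample t test
#'
#' Welch's t test by default (robust to the unequal group sizes and
#' variances typical of age-by-BMI subgroups); set `pooled = TRUE` for the
#' equal-variance variant. The estimate is `mean(x) - mean(y)`.
#'
#' @param x,y numeric samples, each with at least two values and positive
#'   variance.
#' @param pooled use the pooled-variance (Student) test.
#' @param family_size Bonferroni family size for `p_adjusted`.
#' @return one-row tibble with `estimate`, `ci_low`, `ci_high`, `p_raw`,
#'   `p_adjusted`, `family_size`, `method`.
#' @export
two_sample_t <- function(x, y, pooled = FALSE, family_size = 1L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort("each sample needs at least 2 non-missing values.")
  }
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    # Degenerate but well-defined case: identical constant samples.
    return(comparison_result(0, 0, 0, 1,
      method = if (pooled) "t_pooled" else "t_welch",
      family_size = family_size
    ))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    abort("both samples are constant; the t test is degenerate.")
  }
  fit <- t.test(x, y, var.equal = pooled)
  comparison_result(
    estimate = unname(fit$estimate[1] - fit$estimate[2]),
    ci_low = fit$conf.int[1], ci_high = fit$conf.int[2],
    p_raw = fit$p.value,
    method = if (pooled) "t_pooled" else "t_welch",
    family_size = family_size
  )
}

#' Two-sample test of proportions
#'
#' Two-sided z test on the pooled proportion,
#' \eqn{z = (\hat p_1 - \hat p_2) / \sqrt{\bar p (1-\bar p)(1/n_1 + 1/n_2)}},
#' with a Wald confidence interval (unpooled standard error) on the risk
#' difference. No continuity correction.
#'
#' @param k1,n1 events and total in group 1.
#' @param k2,n2 events and total in group 2.
#' @param family_size Bonferroni family size.
#' @return one-row tibble as in [two_sample_t()], with extra columns
#'   `p1`, `p2` and `z`.
#' @export
proportion_test <- function(k1, n1, k2, n2, family_size = 1L) {
  if (n1 <= 0 || n2 <= 0) abort("group totals must be positive.")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    abort("event counts must lie in [0, n].")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pbar <- (k1 + k2) / (n1 + n2)
  se_pooled <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- if (se_pooled == 0) 0 else (p1 - p2) / se_pooled
  p <- 2 * pnorm(-abs(z))
  se_wald <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  comparison_result(
    estimate = p1 - p2,
    ci_low = (p1 - p2) - qnorm(0.975) * se_wald,
    ci_high = (p1 - p2) + qnorm(0.975) * se_wald,
    p_raw = p, method = "prop_z", family_size = family_size,
    p1 = p1, p2 = p2, z = z
  )
}

#' Bonferroni adjustment
#'
#' Multiplies each p value by the family size and caps at 1. With family
#' size 1 this is the identity; the adjustment is monotone, so the ordering
#' of p values is preserved.
#'
#' @param p_values p values in \[0, 1\].
#' @param family_size number of comparisons in the family (>= 1).
#' @return adjusted p values.
#' @export
bonferroni_adjust <- function(p_values, family_size) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].")
  }
  if (family_size < 1) abort("`family_size` must be >= 1.")
  pmin(1, p_values * family_size)
}

#' Crude odds ratio from a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with the Woolf (log-scale Wald)
#' 95% confidence interval. If any cell is zero the Haldane-Anscombe
#' correction adds 0.5 to every cell; the result is flagged in the
#' `corrected` column.
#'
#' @param a,b,c,d cell counts: exposed-event, exposed-nonevent,
#'   unexposed-event, unexposed-nonevent.
#' @param family_size Bonferroni family size.
#' @return one-row tibble; `estimate` is the odds ratio, `corrected` marks
#'   the Haldane adjustment.
#' @export
crude_or <- function(a, b, c, d, family_size = 1L) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("cell counts must be non-negative integers.")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  comparison_result(
    estimate = or,
    ci_low = exp(log(or) - qnorm(0.975) * se),
    ci_high = exp(log(or) + qnorm(0.975) * se),
    p_raw = 2 * pnorm(-abs(z)),
    method = "crude_or", family_size = family_size,
    corrected = corrected
  )
}

#' Odds ratios from a logistic regression
#'
#' Maximum-likelihood logit fit of a binary outcome on a categorical
#' exposure (odds ratio per level against the declared reference) plus
#' optional adjustment covariates, with Wald 95% confidence intervals on
#' the log-odds scale. Complete cases only; covariates listed in
#' `exclude_covariates` (e.g. the variables that define the exposure) are
#' dropped from the adjustment set. Quasi-complete separation is detected
#' by non-convergence or runaway coefficients and reported as a flagged row
#' without an estimate.
#'
#' @param data a data frame.
#' @param outcome name of a binary (logical or 0/1) outcome column.
#' @param exposure name of the exposure column (coerced to factor).
#' @param covariates character vector of adjustment covariate names.
#' @param reference reference level of the exposure (default: first level).
#' @param exclude_covariates covariates to drop from the adjustment set.
#' @return tibble with one row per non-reference exposure level: `level`,
#'   `estimate` (OR), `ci_low`, `ci_high`, `p_raw`, `n_used`, `separation`,
#'   plus a `covariates` attribute echoing the resolved adjustment set.
#' @export
fit_logistic_or <- function(data, outcome, exposure,
                            covariates = character(), reference = NULL,
                            exclude_covariates = character()) {
  covariates <- setdiff(covariates, c(exposure, outcome, exclude_covariates))
  cols <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("columns not in data: %s", paste(missing_cols, collapse = ", ")))
  }
  df <- data[cols]
  df <- df[complete.cases(df), , drop = FALSE]
  y <- df[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) abort("`outcome` must be binary.")
  df[[outcome]] <- y
  expo <- factor(df[[exposure]])
  if (!is.null(reference)) expo <- stats::relevel(expo, ref = reference)
  df[[exposure]] <- expo
  n_param <- nlevels(expo) + length(covariates)
  if (nrow(df) < 10 * n_param) {
    warn(sprintf(
      "only %d complete cases for %d parameters; estimates may be unstable.",
      nrow(df), n_param
    ))
  }
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  levels_out <- levels(expo)[-1L]
  terms <- paste0(exposure, levels_out)
  est <- unname(cf[terms])
  ses <- unname(se[terms])
  separated <- !fit$converged | !is.finite(est) | abs(est) > 15 | ses > 100
  res <- tibble::tibble(
    level = levels_out,
    estimate = ifelse(separated, NA_real_, exp(est)),
    ci_low = ifelse(separated, NA_real_, exp(est - qnorm(0.975) * ses)),
    ci_high = ifelse(separated, NA_real_, exp(est + qnorm(0.975) * ses)),
    p_raw = ifelse(separated, NA_real_, 2 * pnorm(-abs(est / ses))),
    n_used = nrow(df),
    separation = unname(separated)
  )
  attr(res, "covariates") <- covariates
  attr(res, "reference") <- levels(expo)[1L]
  res
}

#' Pearson correlation with test
#'
#' @param x,y numeric samples (pairwise complete, n >= 3, positive
#'   variances). Two-sided p value from the t transform of r.
#' @param family_size Bonferroni family size.
#' @return one-row tibble; `estimate` is r.
#' @export
pearson_corr <- function(x, y, family_size = 1L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("degenerate variance.")
  fit <- cor.test(x, y, method = "pearson")
  ci <- if (!is.null(fit$conf.int)) fit$conf.int else c(NA_real_, NA_real_)
  comparison_result(
    estimate = unname(fit$estimate),
    ci_low = ci[1], ci_high = ci[2],
    p_raw = fit$p.value, method = "pearson",
    family_size = family_size
  )
}

#' Multiple linear regression coefficients
#'
#' Ordinary least squares of a continuous outcome on covariates, complete
#' cases, with 95% confidence intervals. A rank-deficient design (aliased
#' coefficient) is flagged per row.
#'
#' @param data a data frame.
#' @param outcome name of the continuous outcome column.
#' @param covariates character vector of covariate names.
#' @return tibble with one row per coefficient (including the intercept):
#'   `term`, `estimate`, `ci_low`, `ci_high`, `p_raw`, `n_used`, `aliased`.
#' @export
fit_linear <- function(data, outcome, covariates) {
  cols <- c(outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("columns not in data: %s", paste(missing_cols, collapse = ", ")))
  }
  df <- data[cols]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) <= length(covariates) + 1L) {
    abort("not enough complete cases for the number of parameters.")
  }
  fml <- stats::reformulate(covariates, response = outcome)
  fit <- lm(fml, data = df)
  cf <- coef(fit)
  aliased <- is.na(cf)
  if (any(aliased)) {
    warn("rank-deficient design: aliased coefficients flagged.")
  }
  sm <- summary(fit)$coefficients
  ci <- suppressWarnings(confint(fit))
  out <- tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    ci_low = ci[names(cf), 1],
    ci_high = ci[names(cf), 2],
    p_raw = NA_real_,
    n_used = nrow(df),
    aliased = unname(aliased)
  )
  out$p_raw[!aliased] <- sm[, "Pr(>|t|)"][match(out$term[!aliased], rownames(sm))]
  out
}
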