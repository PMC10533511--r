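test_that("t test matches a hand-computed Welch statistic", {
  # Identical samples: zero difference, p = 1.
  x <- c(1.2, 1.9, 3.1, 4.4, 5.0)
  res <- two_sample_t(x, x)
  expect_equal(res$estimate, 0)
  expect_equal(res$p_raw, 1)

  # Hand computation from the Welch formulas.
  y <- c(2.5, 4.1, 5.9, 8.2, 10.0)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / 4; vy <- sum((y - my)^2) / 4
  se2 <- vx / 5 + vy / 5
  t_hand <- (mx - my) / sqrt(se2)
  df_hand <- se2^2 / ((vx / 5)^2 / 4 + (vy / 5)^2 / 4)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  res <- two_sample_t(x, y)
  expect_equal(res$estimate, mx - my, tolerance = 1e-12)
  expect_equal(res$p_raw, p_hand, tolerance = 1e-6)

  # Pooled variant against the pooled closed form.
  sp2 <- (4 * vx + 4 * vy) / 8
  t_pool <- (mx - my) / sqrt(sp2 * (2 / 5))
  expect_equal(
    two_sample_t(x, y, pooled = TRUE)$p_raw,
    2 * stats::pt(-abs(t_pool), 8),
    tolerance = 1e-6
  )

  expect_error(two_sample_t(1, x), "at least 2")
})

test_that("shifting one sample strictly decreases the t-test p value", {
  set.seed(17)
  x <- rnorm(40)
  y0 <- rnorm(40)
  p <- vapply(c(0.5, 1, 2), function(d) two_sample_t(x, y0 + d)$p_raw, 0)
  expect_true(all(diff(p) < 0))
})

test_that("proportion z test: null identity and the printed-counts contrast", {
  res <- proportion_test(10, 50, 20, 100)
  expect_equal(res$z, 0)
  expect_equal(res$p_raw, 1)

  # Primary-cesarean style contrast: 535/2082 vs 883/4226.
  res <- proportion_test(535, 2082, 883, 4226)
  expect_equal(res$estimate, 535 / 2082 - 883 / 4226, tolerance = 1e-12)
  expect_equal(res$estimate, 0.0481, tolerance = 0.005)
  expect_gt(res$estimate, 0)
  expect_lt(res$p_raw, 0.001)

  expect_error(proportion_test(5, 0, 1, 10), "positive")
  expect_error(proportion_test(11, 10, 1, 10), "\\[0, n\\]")
})

test_that("small-sample z test agrees with an exact enumeration oracle", {
  # Unconditional exact two-sided p under the pooled null, by full
  # enumeration of both binomials.
  exact_enum_p <- function(k1, n1, k2, n2) {
    phat <- (k1 + k2) / (n1 + n2)
    obs <- abs(k1 / n1 - k2 / n2)
    g1 <- stats::dbinom(0:n1, n1, phat)
    g2 <- stats::dbinom(0:n2, n2, phat)
    diff <- abs(outer(0:n1 / n1, 0:n2 / n2, "-"))
    sum(outer(g1, g2)[diff >= obs - 1e-12])
  }
  set.seed(7)
  agree <- logical(300)
  for (i in seq_along(agree)) {
    n1 <- sample(10:30, 1)
    n2 <- sample(10:30, 1)
    k1 <- rbinom(1, n1, runif(1, 0.1, 0.9))
    k2 <- rbinom(1, n2, runif(1, 0.1, 0.9))
    pz <- proportion_test(k1, n1, k2, n2)$p_raw
    pe <- exact_enum_p(k1, n1, k2, n2)
    agree[i] <- (pz < 0.05) == (pe < 0.05)
  }
  expect_gte(mean(agree), 0.95)
})

test_that("Bonferroni multiplies, caps at 1, and preserves ordering", {
  expect_equal(bonferroni_adjust(0.01, 6), 0.06)
  expect_equal(bonferroni_adjust(0.4, 6), 1)
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- bonferroni_adjust(p, 6)
  expect_true(all(adj >= p))
  expect_equal(order(adj), order(p))
  expect_equal(bonferroni_adjust(p, 1), p)
  expect_error(bonferroni_adjust(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(0.2, 0), ">= 1")
})

test_that("crude odds ratio: symmetry, cross-product value, Haldane correction", {
  expect_equal(crude_or(7, 7, 7, 7)$estimate, 1)

  # LGA-style 2x2: 26/215 exposed vs 169/4226 unexposed.
  res <- crude_or(26, 189, 169, 4057)
  expect_equal(res$estimate, (26 * 4057) / (189 * 169), tolerance = 1e-12)
  expect_equal(round(res$estimate, 2), 3.30)
  # Woolf CI against the closed form.
  se <- sqrt(1 / 26 + 1 / 189 + 1 / 169 + 1 / 4057)
  expect_equal(res$ci_low, exp(log(res$estimate) - qnorm(0.975) * se),
    tolerance = 1e-12)

  res0 <- crude_or(0, 20, 5, 15)
  expect_true(res0$corrected)
  expect_true(is.finite(res0$estimate))
  expect_equal(res0$estimate, (0.5 * 15.5) / (20.5 * 5.5), tolerance = 1e-12)
  expect_error(crude_or(-1, 2, 3, 4), "non-negative")
})

test_that("single-predictor logistic fit equals the crude 2x2 odds ratio", {
  set.seed(23)
  n <- 400
  exposed <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, ifelse(exposed == 1, 0.35, 0.15))
  d <- tibble::tibble(y = y, exposed = factor(exposed, levels = c(0, 1)))
  fit <- fit_logistic_or(d, "y", "exposed", reference = "0")
  a <- sum(y == 1 & exposed == 1)
  b <- sum(y == 0 & exposed == 1)
  cc <- sum(y == 1 & exposed == 0)
  dd <- sum(y == 0 & exposed == 0)
  oracle <- crude_or(a, b, cc, dd)
  expect_equal(fit$estimate, oracle$estimate, tolerance = 1e-6)
})

test_that("logistic fit recovers planted subgroup odds ratios at n = 20000", {
  cfg <- generator_config(n = 20000, seed = 101)
  cohort <- generate_cohort(cfg)
  truth <- attr(cohort, "truth")
  planted <- planted_truth(cfg)
  # Fit the generating model: outcome ~ subgroup + true FAO status.
  fit <- fit_logistic_or(truth, "lga_true", "group",
    covariates = "fao_true", reference = "G1"
  )
  for (i in 1:3) {
    expect_gte(planted$lga_or[i + 1], fit$ci_low[i])
    expect_lte(planted$lga_or[i + 1], fit$ci_high[i])
  }
})

test_that("categorized-exposure logistic recovers a planted adjusted OR", {
  set.seed(29)
  n <- 20000
  band <- sample(c("<30", "30-35", "35-40", ">40"), n,
    replace = TRUE, prob = c(0.25, 0.45, 0.25, 0.05)
  )
  band <- factor(band, levels = c("<30", "30-35", "35-40", ">40"))
  x <- rnorm(n, mean = 0.3 * (as.integer(band) - 1)) # confounder
  eta <- -2.6 + log(1.2) * (band == "30-35") + log(1.55) * (band == "35-40") +
    log(1.3) * (band == ">40") + 0.4 * x
  y <- rbinom(n, 1, plogis(eta))
  d <- tibble::tibble(y = y, band = band, x = x)
  fit <- fit_logistic_or(d, "y", "band", covariates = "x", reference = "<30")
  row <- fit[fit$level == "35-40", ]
  expect_gte(1.55, row$ci_low)
  expect_lte(1.55, row$ci_high)
  expect_equal(attr(fit, "covariates"), "x")
})

test_that("logistic separation is flagged rather than estimated", {
  d <- tibble::tibble(
    y = c(rep(0, 20), rep(1, 20)),
    g = factor(c(rep("a", 20), rep("b", 20)))
  )
  fit <- suppressWarnings(fit_logistic_or(d, "y", "g", reference = "a"))
  expect_true(fit$separation)
  expect_true(is.na(fit$estimate))
})

test_that("Pearson correlation: exact linear cases and the null band", {
  x <- c(0.3, 1.1, 2.7, 3.1, 4.9, 6.2)
  expect_equal(pearson_corr(x, x)$estimate, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -2 * x + 3)$estimate, -1, tolerance = 1e-12)
  expect_error(pearson_corr(x, rep(2, 6)), "degenerate")

  set.seed(37)
  r <- pearson_corr(rnorm(1000), rnorm(1000))$estimate
  expect_lt(abs(r), 0.08)
})

test_that("linear model recovers exact and planted coefficients", {
  set.seed(41)
  n <- 200
  d <- tibble::tibble(a = rnorm(n), b = runif(n), c = rnorm(n))
  d$y <- 2 - 1.5 * d$a + 0.25 * d$b # noiseless, c irrelevant
  fit <- suppressWarnings(fit_linear(d, "y", c("a", "b"))) # perfect fit
  expect_equal(fit$estimate, c(2, -1.5, 0.25), tolerance = 1e-8)

  # Planted model with noise at n = 20000: estimator bias (averaged over
  # replicates, since a single draw sits at ~1 SE) under 10% of each effect.
  n <- 20000
  beta <- c(age = 0.0015, bmi = 0.0015, gain = 0.0008)
  sim_fit <- function() {
    d <- tibble::tibble(
      age = rnorm(n, 33, 4), bmi = rnorm(n, 21, 2.5), gain = rnorm(n, 7.5, 3)
    )
    d$faor <- 0.93 + beta["age"] * d$age + beta["bmi"] * d$bmi +
      beta["gain"] * d$gain + rnorm(n, 0, 0.036)
    list(d = d, fit = fit_linear(d, "faor", c("age", "bmi", "gain")))
  }
  reps <- lapply(1:20, function(i) sim_fit())
  for (v in names(beta)) {
    est <- mean(vapply(reps, function(r) r$fit$estimate[r$fit$term == v], 0))
    expect_lt(abs(est - beta[[v]]), 0.1 * beta[[v]])
  }

  # An irrelevant covariate leaves recovery inside the CI.
  d <- reps[[1]]$d
  d$junk <- rnorm(n)
  fit2 <- fit_linear(d, "faor", c("age", "bmi", "gain", "junk"))
  for (v in names(beta)) {
    row <- fit2[fit2$term == v, ]
    expect_gte(beta[[v]], row$ci_low)
    expect_lte(beta[[v]], row$ci_high)
  }
})

test_that("collinear designs are flagged as aliased", {
  d <- tibble::tibble(a = rnorm(50))
  d$b <- 2 * d$a
  d$y <- d$a + rnorm(50)
  expect_warning(fit <- fit_linear(d, "y", c("a", "b")), "rank-deficient")
  expect_true(any(fit$aliased))
})

test_that("confidence intervals attain nominal coverage on planted truth", {
  set.seed(43)
  reps <- 1000
  # Risk-difference Wald CI, n = 2000 per arm, true difference 0.10.
  k1 <- rbinom(reps, 2000, 0.30)
  k2 <- rbinom(reps, 2000, 0.20)
  p1 <- k1 / 2000
  p2 <- k2 / 2000
  se <- sqrt(p1 * (1 - p1) / 2000 + p2 * (1 - p2) / 2000)
  covered <- abs((p1 - p2) - 0.10) <= qnorm(0.975) * se
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)

  # Welch CI for a mean difference of 0.5 at n = 200 per arm.
  covered_t <- vapply(seq_len(reps), function(i) {
    res <- two_sample_t(rnorm(200, 0.5), rnorm(200))
    res$ci_low <= 0.5 && 0.5 <= res$ci_high
  }, logical(1))
  expect_gte(mean(covered_t), 0.93)
  expect_lte(mean(covered_t), 0.97)
})
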