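# Shared fixtures: tiny charts and hand-built cohorts.

# Minimal 3-knot chart around 25-27 weeks.
tiny_chart <- function(kind = "ac") {
  growth_chart(c(175, 182, 189), c(40, 43, 46), kind)
}

# A quiet generator: no measurement noise, no planted ratio variation, no
# exclusions -- every derived ratio should be exactly 1.
quiet_config <- function(n = 50, seed = 1) {
  generator_config(
    n = n, seed = seed,
    faor_model = list(intercept = 1, age = 0, bmi = 0, gain = 0, gct = 0, sd = 0),
    head_ga_scale = 1, head_ga_scale_sd = 0,
    biometry_noise_sd_mm = 0,
    biometry_missing_rate = 0, near_missing_rate = 0,
    faor_persist = 1, faor_near_sd = 0,
    exclusion_rates = c(
      pih = 0, no_weight = 0, no_gct = 0, no_ogtt = 0,
      one_value = 0, gdm = 0, elsewhere = 0
    )
  )
}

# Independent type-7 quantile oracle: sort + linear interpolation between
# order statistics, written from the definition.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo == n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
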