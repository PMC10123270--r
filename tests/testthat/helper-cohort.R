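# Shared fixtures, built in code.

# Small hand-written cohort with exact values for derived-variable checks.
toy_cohort <- function() {
  data.frame(
    subject_id = c("A1", "A2", "A3", "A4", "A5", "A6", "A7", "A8"),
    eye = "OD",
    age = c(18, 25, 31, 22, 40, 19, 27, 35),
    gender = c("female", "male", "female", "male",
               "female", "male", "female", "male"),
    ser_d = c(-6.04, 0, -2.5, -8.1, -0.75, -11.2, -4.4, -1.1),
    ssi = c(0.82, 0.95, 0.70, 0.65, 1.05, 0.55, 0.88, 0.99),
    cct_um = c(544, 560, 520, 505, 580, 498, 551, 566),
    cr_mm = c(7.78, 7.76, 7.90, 7.45, 8.10, 7.60, 7.70, 7.85),
    al_mm = c(26.01, 23.60, 24.80, 27.90, 24.10, 29.50, 25.40, 24.00),
    stringsAsFactors = FALSE
  )
}

# Memoised default synthetic cohorts (generation is fast; cache anyway so
# many tests can share one draw).
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(n = 5000, seed = 20240101) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.cohort_cache[[key]])) {
    cfg <- calibrate_generator(generator_config(n = n, seed = seed))
    .cohort_cache[[key]] <- generate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

# Independent normal-equations OLS oracle: solve X'X beta = X'y directly.
ols_oracle <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1L]
}

# Brute-force Pearson r from the covariance/SD definition.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
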