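# Shared fixtures and independent oracles used across the suite.

# flat life table over a wide age span (q constant, possibly 0)
const_life_table <- function(q, ages = 20:110) {
  structure(data.frame(age = ages, qx = q),
            class = c("hd_life_table", "data.frame"))
}

# brute-force OLS slope via the normal equations (independent of lm)
ols_slope_oracle <- function(t, y) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  unname(beta[2, 1])
}

# parameters with an exactly linear trajectory (slope given), zero CI
linear_params <- function(population, slope, start_tfc = NULL, ...) {
  tr <- data.frame(time_years = c(0, 1, 3),
                   mean_delta = c(0, slope, 3 * slope),
                   ci_lower = NA_real_, ci_upper = NA_real_)
  hd_parameters(population, trajectories = tr, start_tfc = start_tfc, ...)
}

# PFD parameter set plus a hand-built schedule with given weights
manual_schedule <- function(weights, start_age = 40, max_age = 100) {
  n <- max_age - start_age
  w <- numeric(n)
  w[seq_along(weights)] <- weights
  hdcohort:::new_onset_schedule(start_age, w,
                                residual_weight = 1 - sum(weights))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
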