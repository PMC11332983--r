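test_that("credible_range follows the interpolated-quantile rule", {
  expect_equal(credible_range(rep(3.5, 10)), c(lower = 3.5, upper = 3.5))
  expect_equal(credible_range(1:1000), c(lower = 25.975, upper = 975.025),
               tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(500)
  expect_identical(credible_range(x), credible_range(sample(x)))
  # independent sort-based oracle for the type-7 rule
  xs <- sort(x)
  h <- function(p) { i <- 1 + (length(xs) - 1) * p
                     lo <- floor(i); xs[lo] + (i - lo) * (xs[lo + 1] - xs[lo]) }
  expect_equal(unname(credible_range(x)), c(h(0.025), h(0.975)),
               tolerance = 1e-12)
  expect_error(credible_range(numeric(0)), "empty")
})

test_that("sample_parameters is deterministic and collapses at zero variance", {
  params <- hd_parameters("SF1")
  spec0 <- psa_spec(5, seed = 3,
                    registry = default_distribution_registry("SF1",
                                                             zero_variance = TRUE))
  d <- sample_parameters(params, spec0, 1)
  expect_equal(d$trajectories$mean_delta, params$trajectories$mean_delta)
  expect_equal(d$payoffs, params$payoffs)

  spec <- psa_spec(5, seed = 3)
  d1 <- sample_parameters(params, spec, 2)
  d2 <- sample_parameters(params, spec, 2)
  expect_identical(d1, d2)
  d3 <- sample_parameters(params, spec, 3)
  expect_false(identical(d1$trajectories$mean_delta, d3$trajectories$mean_delta))
})

test_that("trajectory deltas stay perfectly correlated and the SLR is re-fit", {
  params <- hd_parameters("SF1")
  spec <- psa_spec(50, seed = 11)
  for (i in c(1, 17, 42)) {
    d <- sample_parameters(params, spec, i)
    d12 <- d$trajectories$mean_delta[d$trajectories$time_years == 1]
    d36 <- d$trajectories$mean_delta[d$trajectories$time_years == 3]
    expect_equal(d36 / d12, -1.989 / -0.910, tolerance = 1e-12)
    # recomputed slope scales by the same factor
    expect_equal(fit_tfc_slope(d), -0.6453571 * d12 / -0.910, tolerance = 1e-6)
  }
})

test_that("sampled inputs converge to their base-case means", {
  params <- hd_parameters("SF1")
  spec <- psa_spec(10000, seed = 21)
  n <- 10000
  u <- numeric(n); d12 <- numeric(n)
  for (i in seq_len(n)) {
    d <- sample_parameters(params, spec, i)
    u[i] <- d$payoffs$utility[["SF1"]]
    d12[i] <- d$trajectories$mean_delta[d$trajectories$time_years == 1]
  }
  expect_lt(abs(mean(u) - 0.78), 3 * sd(u) / sqrt(n))
  expect_lt(abs(mean(d12) - -0.910), 3 * sd(d12) / sqrt(n))
})

test_that("zero-variance PSA collapses credible ranges to the base case", {
  params <- hd_parameters("SF1")
  spec <- psa_spec(5, seed = 1,
                   registry = default_distribution_registry("SF1", TRUE))
  res <- run_psa(params, spec, hd_life_table())
  expect_length(res$failures, 0)
  expect_equal(res$summary$cr_lower, res$summary$base_case, tolerance = 1e-12)
  expect_equal(res$summary$cr_upper, res$summary$base_case, tolerance = 1e-12)
})

test_that("PSA summaries are seed-deterministic and match a sorting oracle", {
  params <- hd_parameters("SF2")
  lt <- hd_life_table()
  r1 <- run_psa(params, psa_spec(40, seed = 9), lt)
  r2 <- run_psa(params, psa_spec(40, seed = 9), lt)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$simulations, r2$simulations)

  x <- r1$simulations$life_years_disc
  expect_equal(unname(credible_range(x)),
               unname(quantile(x, c(0.025, 0.975), type = 7)),
               tolerance = 1e-12)
  row <- r1$summary[r1$summary$output == "life_years_disc", ]
  expect_equal(row$cr_lower, unname(quantile(x, 0.025)), tolerance = 1e-12)
})

test_that("credible ranges widen weakly with input variance", {
  params <- hd_parameters("SF1")
  lt <- hd_life_table()
  reg_half <- default_distribution_registry("SF1")
  reg_half$tfc_delta_12mo$sd <- reg_half$tfc_delta_12mo$sd / 2
  narrow <- run_psa(params, psa_spec(150, seed = 4, registry = reg_half), lt)
  wide <- run_psa(params, psa_spec(150, seed = 4), lt)
  w <- function(r, v) { s <- r$summary[r$summary$output == v, ]
                        s$cr_upper - s$cr_lower }
  for (v in c("life_years_disc", "qalys_disc"))
    expect_lte(w(narrow, v), w(wide, v))
})

test_that("failed simulations are surfaced, not dropped", {
  params <- hd_parameters("SF1")
  reg <- default_distribution_registry("SF1", zero_variance = TRUE)
  reg$utility_SF1 <- structure(list(family = "bogus", base_value = 0.5),
                               class = "hd_dist_spec")
  res <- run_psa(params, psa_spec(4, seed = 2, registry = reg), hd_life_table())
  expect_identical(res$failures, 1:4)
  expect_true(all(is.na(res$simulations$life_years_disc)))
})

test_that("tornado analysis: zero-width bars, cost linearity, ranking", {
  lt <- hd_life_table()
  # SF2 cohorts never occupy SF1-stage states: those payoffs cannot matter
  tab <- run_owsa(hd_parameters("SF2"), lt, outcome = "cost_total_disc")
  expect_s3_class(tab, "hd_tornado_table")
  expect_true(all(order(-abs(tab$width)) == seq_len(nrow(tab))))
  z <- tab[tab$parameter %in% c("utility_SF1", "direct_cost_SF1",
                                "societal_cost_SF1"), "width"]
  expect_equal(z, rep(0, 3), tolerance = 1e-12)

  # cost accrual is linear: +/-25% on a stage cost moves that stage's
  # contribution by exactly +/-25%
  base <- evaluate_model(hd_parameters("SF2"), lt)
  contrib <- base$costs$discounted[base$costs$category == "direct" &
                                     base$costs$stage == "SF3"]
  row <- tab[tab$parameter == "direct_cost_SF3", ]
  expect_equal(row$width, 0.5 * contrib, tolerance = 1e-9)
  expect_equal(row$outcome_high - unname(base$cost_total["discounted"]),
               0.25 * contrib, tolerance = 1e-9)

  # utilities cap at 1 when varied upward
  tab_u <- run_owsa(hd_parameters("SF1"), lt, outcome = "qalys_disc")
  expect_true(all(tab_u$high_value[tab_u$parameter == "utility_PFD"] >= 1))
})

test_that("DMT tornado ranks efficacy parameters among the widest bars", {
  tab <- run_owsa(hd_parameters("SF1"), hd_life_table(), scenario = "A",
                  outcome = "qalys_disc")
  top <- tab$parameter[1:4]
  expect_true("rate_ratio" %in% top)
  expect_true("delay_years" %in% top)
})
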