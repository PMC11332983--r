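test_that("deterministic stepping: p = 1, q = 0 kills a TFC-3 cohort at t = 3", {
  params <- linear_params("SF2", -1, start_tfc = NULL)
  params$start_tfc <- 3L  # bypass population range check on purpose
  trace <- run_cohort(params, const_life_table(0))
  S <- survival_curve(trace)
  expect_equal(S[1:3], c(1, 1, 1), tolerance = 1e-12)
  expect_equal(S[4], 0, tolerance = 1e-12)
  expect_equal(trace$dead_hd[4], 1, tolerance = 1e-12)
  expect_equal(trace$dead_bg[4], 0)
  expect_equal(sum(trace$entry_to_death), 1, tolerance = 1e-12)
})

test_that("p = 0, q = 0 leaves occupancy constant", {
  params <- linear_params("SF1", 0)
  trace <- run_cohort(params, const_life_table(0))
  expect_true(all(trace$occupancy[, "tfc12"] == 1))
  expect_equal(median_survival(trace), Inf)
})

test_that("mass conservation, survival monotonicity, dead monotone", {
  lt <- hd_life_table()
  traces <- list(
    run_cohort(hd_parameters("SF1"), lt),
    run_cohort(hd_parameters("SF2", dmt = dmt_scenario(3, 0.75)), lt),
    run_pfd_cohort(hd_parameters("PFD"),
                   default_onset_schedule(hd_parameters("PFD")), lt)
  )
  for (tr in traces) {
    total <- rowSums(tr$occupancy) + tr$dead_hd + tr$dead_bg
    expect_lt(max(abs(total - 1)), 1e-12)
    expect_true(all(diff(survival_curve(tr)) <= 1e-12))
    expect_true(all(diff(tr$dead_hd) >= -1e-15))
    expect_true(all(diff(tr$dead_bg) >= -1e-15))
  }
})

test_that("median survival interpolates linearly and handles no-crossing", {
  S <- c(rep(1, 10), 0.4, 0.1)  # S(9) = 1, S(10) = 0.4
  expect_equal(median_survival(S), 9 + 0.5 / 0.6, tolerance = 1e-12)
  expect_identical(median_survival(rep(1, 5)), Inf)
  expect_error(median_survival(c(0.9, 0.4)), "start at 1")
})

test_that("cohort time-to-death matches negative-binomial oracles (q = 0)", {
  k <- 5L; p <- 0.6
  params <- linear_params("SF2", -p)
  params$start_tfc <- k
  trace <- run_cohort(params, const_life_table(0))
  # undiscounted person-years = E[cycles to absorb] = k/p (horizon tail tiny)
  out <- accumulate_outcomes(trace, discount_rate = 0)
  expect_equal(unname(out$life_years["undiscounted"]), k / p, tolerance = 1e-4)
  # Monte-Carlo median of k + NB(k, p) failures vs interpolated cohort median
  set.seed(99)
  mc <- k + rnbinom(1e5, size = k, prob = p)
  expect_lt(abs(median_survival(trace) - median(mc)), 1)
  # exact CDF cross-check: S(t) = P(NB arrivals > t)
  S <- survival_curve(trace)
  expect_equal(S[11], 1 - pnbinom(10 - k, size = k, prob = p),
               tolerance = 1e-12)
})

test_that("accrual identities: unit utilities, zero discount, disc <= undisc", {
  lt <- hd_life_table()
  trace <- run_cohort(hd_parameters("SF1"), lt)
  pay <- default_payoffs()
  pay$utility[] <- 1
  out0 <- accumulate_outcomes(trace, pay, discount_rate = 0)
  expect_equal(out0$qalys, out0$life_years, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(out0$cost_total["discounted"]),
               unname(out0$cost_total["undiscounted"]), tolerance = 1e-12)

  out <- accumulate_outcomes(trace, default_payoffs(), discount_rate = 0.03)
  expect_lt(out$qalys["discounted"], out$life_years["discounted"])
  for (f in c("life_years", "qalys", "cost_total", "cost_direct", "cost_societal"))
    expect_lte(out[[f]]["discounted"], out[[f]]["undiscounted"])
  # total equals the sum over category x stage cells
  expect_rel(sum(out$costs$discounted), unname(out$cost_total["discounted"]), 1e-9)
})

test_that("stage-time identity: discounted SF1-stage years = QALYs / utility", {
  lt <- hd_life_table()
  params <- hd_parameters("SF1")
  trace <- run_cohort(params, lt)
  out <- accumulate_outcomes(trace, params$payoffs, 0.03)
  q_sf1 <- out$qalys_by_stage$discounted[out$qalys_by_stage$stage == "SF1"]
  # direct occupancy sum over the SF1-stage states (TFC 13-11)
  T <- nrow(trace$occupancy) - 1
  disc <- 1.03^-(0:(T - 1))
  yrs <- sum(trace$occupancy[1:T, c("tfc13", "tfc12", "tfc11")] * disc)
  expect_equal(q_sf1 / 0.78, yrs, tolerance = 1e-9)
  # and the published-scale check: about 2.96 discounted years (2.31 / 0.78)
  expect_equal(yrs, 2.31 / 0.78, tolerance = 0.02)
})

test_that("SF5 terminal cost option charges entry-to-death mass once", {
  lt <- const_life_table(0)
  params <- linear_params("SF1", -0.651)
  trace <- run_cohort(params, lt)
  base <- accumulate_outcomes(trace, params$payoffs, 0, sf5_terminal_cost = FALSE)
  term <- accumulate_outcomes(trace, params$payoffs, 0, sf5_terminal_cost = TRUE)
  dead_mass <- sum(trace$entry_to_death)
  expect_equal(unname(term$cost_total["undiscounted"] - base$cost_total["undiscounted"]),
               dead_mass * (25217 + 36409), tolerance = 1e-9)
  expect_true("SF5" %in% term$costs$stage)
  expect_false("SF5" %in% base$costs$stage)
})

test_that("PFD pooling: single-subcohort collapse and mortality-only limit", {
  lt <- hd_life_table()
  pfd <- hd_parameters("PFD")
  # all onset mass at k = 0: pooled trace equals an SF1-rate cohort at TFC 13
  tr_pfd <- run_pfd_cohort(pfd, manual_schedule(1), lt)
  sf1 <- hd_parameters("SF1", start_tfc = 13)
  tr_sf1 <- run_cohort(sf1, lt)
  expect_equal(tr_pfd$occupancy[, -1], tr_sf1$occupancy[, -1], tolerance = 1e-12)
  expect_equal(survival_curve(tr_pfd), survival_curve(tr_sf1), tolerance = 1e-12)

  # all residual: survival is pure background mortality
  tr_none <- run_pfd_cohort(pfd, manual_schedule(numeric(0)), lt)
  q <- lt$qx[match(40:99, lt$age)]
  expect_equal(survival_curve(tr_none), c(1, cumprod(1 - q)), tolerance = 1e-12)
  expect_equal(sum(tr_none$entry_to_death), 0)
})

test_that("PFD pooling matches an explicit two-subcohort mixture oracle", {
  lt <- hd_life_table()
  pfd <- hd_parameters("PFD")
  tr <- run_pfd_cohort(pfd, manual_schedule(c(0.5, 0, 0, 0, 0, 0.5)), lt)

  # oracle: average of two hand-shifted SF1-rate traces
  p <- progression_model(pfd)$annual_transition_probability
  q <- lt$qx[match(40:99, lt$age)]
  shifted <- function(k) {
    pre <- c(1, cumprod(1 - q))[k + 1]
    occ <- matrix(0, 61, 14)
    if (k > 0) occ[1:k, 1] <- c(1, cumprod(1 - q))[1:k]
    pr <- hdcohort:::propagate_cohort(c(pre, numeric(12)), p, q[(k + 1):60])
    occ[(k + 1):61, 2:14] <- pr$occupancy
    occ
  }
  mix <- 0.5 * shifted(0) + 0.5 * shifted(5)
  expect_equal(unname(tr$occupancy), unname(mix), tolerance = 1e-12)

  expect_error(run_pfd_cohort(pfd, manual_schedule(1, max_age = 90), lt),
               "horizon")
})

test_that("life table reader validates and round-trips", {
  lt <- hd_life_table()
  expect_s3_class(lt, "hd_life_table")
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  expect_equal(read_life_table(path)$qx, lt$qx, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,qx", "40,0.5", "41,1.5"), bad)
  expect_error(read_life_table(bad), "outside")
  gap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,qx", "40,0.01", "42,0.01"), gap)
  expect_error(read_life_table(gap), "contiguous")
  # coverage error surfaces when the horizon exceeds the table
  short <- structure(data.frame(age = 40:50, qx = 0.01),
                     class = c("hd_life_table", "data.frame"))
  expect_error(run_cohort(hd_parameters("SF1"), short), "cover")
})
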