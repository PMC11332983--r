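# Model inputs: TFC/Shoulson-Fahn scale helpers, the packaged base-case
# parameter registry, parameter-set construction/validation, and
# method-of-moments constructors for the PSA sampling distributions.

#' Shoulson–Fahn stage definitions
#'
#' The Shoulson–Fahn (SF) system partitions the 0–13 Total Functional
#' Capacity (TFC) scale into five stages used for cost and utility payoffs:
#' SF1 = TFC 13–11, SF2 = 10–7, SF3 = 6–3, SF4 = 2–1, SF5 = 0. TFC 0 (SF5)
#' is treated as equivalent to death throughout the model.
#'
#' @return A data.frame with columns `stage`, `tfc_min`, `tfc_max`.
#' @export
#' @examples
#' sf_stage_table()
sf_stage_table <- function() {
  data.frame(
    stage   = c("SF1", "SF2", "SF3", "SF4", "SF5"),
    tfc_min = c(11L, 7L, 3L, 1L, 0L),
    tfc_max = c(13L, 10L, 6L, 2L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Map TFC scores to Shoulson–Fahn stages
#'
#' @param tfc Integer vector of TFC scores in 0..13.
#' @return Character vector of stage labels ("SF1".."SF5").
#' @export
#' @examples
#' sf_stage(c(13, 10, 6, 2, 0))
sf_stage <- function(tfc) {
  stopifnot(all(tfc %in% 0:13))
  tab <- sf_stage_table()
  vapply(tfc, function(x) {
    tab$stage[x >= tab$tfc_min & x <= tab$tfc_max]
  }, character(1))
}

# live TFC states in model order (TFC 13 down to 1; TFC 0 is death)
tfc_live_states <- function() 13:1

## ---------------------------------------------------------------------------
## Distribution specifications (PSA building blocks)

new_dist_spec <- function(family, base_value, ...) {
  structure(list(family = family, base_value = base_value, ...),
            class = "hd_dist_spec")
}

# 95% interval width to sd; the conventional 1.96 multiplier is used
# literally so printed intervals convert to the printed-precision sd
ci_halfwidth_sd <- function(lower, upper) (upper - lower) / (2 * 1.96)

#' Normal distribution from a mean and 95% interval
#'
#' Builds a normal sampling specification with the printed mean as location
#' and sd = (upper - lower) / (2 * 1.96). The printed mean is kept even when
#' the interval is asymmetric about it.
#'
#' @param mean,lower,upper Base-case mean and 95% interval bounds.
#' @return An `hd_dist_spec`.
#' @export
#' @examples
#' normal_from_mean_bounds(-0.910, -1.360, -0.620)
normal_from_mean_bounds <- function(mean, lower, upper) {
  if (lower > upper) stop("normal_from_mean_bounds: lower > upper")
  sd <- ci_halfwidth_sd(lower, upper)
  new_dist_spec("normal", mean, mean = mean, sd = sd)
}

#' Beta distribution from a mean and 95% interval (method of moments)
#'
#' With sd = (upper - lower)/3.92 and k = mean(1-mean)/var - 1, the shapes
#' are alpha = mean*k, beta = (1-mean)*k, so the analytic mean equals the
#' base case exactly. A zero-width interval degenerates to a point mass.
#'
#' @inheritParams normal_from_mean_bounds
#' @return An `hd_dist_spec`.
#' @export
beta_from_mean_bounds <- function(mean, lower, upper) {
  if (lower > upper) stop("beta_from_mean_bounds: lower > upper")
  if (mean <= 0 || mean >= 1) stop("beta_from_mean_bounds: mean must be in (0,1)")
  sd <- ci_halfwidth_sd(lower, upper)
  if (sd == 0) return(new_dist_spec("point", mean))
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop("beta_from_mean_bounds: implied variance too large for a beta distribution")
  k <- mean * (1 - mean) / v - 1
  new_dist_spec("beta", mean, shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Log-normal distribution from an arithmetic mean and 95% interval
#'
#' Matches the arithmetic mean and sd = (upper - lower)/3.92:
#' sdlog^2 = log(1 + (sd/mean)^2), meanlog = log(mean) - sdlog^2/2.
#' Lower bounds of 0 should be floored at a small positive value by the
#' caller (log-normal support excludes 0); a zero-width interval degenerates
#' to a point mass.
#'
#' @inheritParams normal_from_mean_bounds
#' @return An `hd_dist_spec`.
#' @export
lognormal_from_mean_bounds <- function(mean, lower, upper) {
  if (lower > upper) stop("lognormal_from_mean_bounds: lower > upper")
  if (mean <= 0) stop("lognormal_from_mean_bounds: mean must be positive")
  sd <- ci_halfwidth_sd(lower, upper)
  if (sd == 0) return(new_dist_spec("point", mean))
  sdlog2 <- log1p((sd / mean)^2)
  new_dist_spec("lognormal", mean,
                meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Analytic mean of a distribution specification
#' @param spec An `hd_dist_spec`.
#' @return The analytic mean (equals the base-case value by construction).
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "hd_dist_spec"))
  switch(spec$family,
    point     = spec$base_value,
    normal    = spec$mean,
    beta      = spec$shape1 / (spec$shape1 + spec$shape2),
    lognormal = exp(spec$meanlog + spec$sdlog^2 / 2),
    stop("unknown family: ", spec$family))
}

#' Draw from a distribution specification
#'
#' Uses the current RNG stream. A point-mass spec (or a normal with sd 0)
#' returns the base value exactly.
#'
#' @param spec An `hd_dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n = 1) {
  stopifnot(inherits(spec, "hd_dist_spec"))
  switch(spec$family,
    point     = rep(spec$base_value, n),
    normal    = if (spec$sd == 0) rep(spec$mean, n) else
                  stats::rnorm(n, spec$mean, spec$sd),
    beta      = stats::rbeta(n, spec$shape1, spec$shape2),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    stop("unknown family: ", spec$family))
}

#' @export
print.hd_dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "base_value"))]
  cat(sprintf("<hd_dist_spec %s> base %.6g  [%s]\n", x$family, x$base_value,
              paste(sprintf("%s=%.6g", names(pars), unlist(pars)), collapse = ", ")))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Packaged base-case registry

#' Packaged base-case parameter registry
#'
#' Every model input with its base-case value, 95% interval (where one is
#' used for probabilistic analysis) and sampling family. Trajectory deltas
#' are mean TFC changes from baseline at 12 and 36 months; the 36-month
#' delta has no interval of its own because it is perfectly correlated with
#' the 12-month draw in the PSA. Costs are annual 2023 USD; utilities are
#' per-year weights in [0,1]. The SF5 direct-cost lower bound of $0 is
#' floored at 1e-6 for log-normal construction.
#'
#' @return A nested list: `general`, `pfd`, `trajectories`, `utility`,
#'   `direct_cost`, `societal_cost`. Rows with bounds carry
#'   `c(base, lower, upper)`.
#' @export
table1_base_case <- function() {
  list(
    general = list(
      start_age = 40, max_age = 100, discount_rate = 0.03,
      owsa_fraction = 0.25, n_simulations = 5000L
    ),
    pfd = list(cag_repeats = 40L, tfc = 13L, tms = 2, sdmt = 50),
    trajectories = list(
      SF1 = list(baseline_tfc = 12.2, start_tfc = 12L,
                 delta_12mo = c(-0.910, -1.360, -0.620), delta_36mo = -1.989),
      SF2 = list(baseline_tfc = 8.7, start_tfc = 9L,
                 delta_12mo = c(-0.440, -0.780, -0.130), delta_36mo = -1.974)
    ),
    utility = list(
      PFD   = c(0.86, 0.84, 0.87),
      SF1   = c(0.78, 0.72, 0.85),
      SF2   = c(0.66, 0.59, 0.73),
      SF3   = c(0.54, 0.48, 0.61),
      SF4_5 = c(0.22, 0.11, 0.32)
    ),
    direct_cost = list(
      SF1 = c(13183, 5723, 20644),
      SF2 = c(16549, 3786, 29311),
      SF3 = c(20189, 5404, 34974),
      SF4 = c(48031, 18983, 77080),
      SF5 = c(25217, 1e-6, 55668)
    ),
    societal_cost = list(
      SF1 = c(30691, 11333, 50048),
      SF2 = c(41676, 15390, 67962),
      SF3 = c(110142, 38727, 185849),
      SF4 = c(58561, 1724, 115398),
      SF5 = c(36409, 1072, 71746)
    )
  )
}

trajectory_df <- function(entry) {
  data.frame(
    time_years = c(0, 1, 3),
    mean_delta = c(0, entry$delta_12mo[1], entry$delta_36mo),
    ci_lower   = c(NA, entry$delta_12mo[2], NA),
    ci_upper   = c(NA, entry$delta_12mo[3], NA)
  )
}

default_payoffs <- function(reg = table1_base_case()) {
  list(
    utility = vapply(reg$utility, `[`, numeric(1), 1),
    direct_cost = vapply(reg$direct_cost, `[`, numeric(1), 1),
    societal_cost = vapply(reg$societal_cost, `[`, numeric(1), 1)
  )
}

## ---------------------------------------------------------------------------
## Parameter sets

#' Construct a validated model parameter set
#'
#' The single source of truth for a model run: population, horizon,
#' discounting, starting state, trajectory observations, stage payoffs and
#' an optional disease-modifying-treatment scenario. Unspecified arguments
#' take the packaged base-case values from [table1_base_case()].
#'
#' The prefunctional-decline (PFD) population starts at TFC 13 with no
#' active decline; at onset it enters TFC 13 and progresses at the SF1
#' rate, so its `trajectories` are the SF1 observations.
#'
#' @param population One of "PFD", "SF1", "SF2".
#' @param start_age,max_age Model entry age and horizon end (years).
#' @param discount_rate Annual discount fraction in [0, 1).
#' @param start_tfc Starting TFC state; defaults to 12 (SF1), 9 (SF2)
#'   (rounded trial baselines 12.2 / 8.7) or 13 (PFD).
#' @param cag_repeats CAG repeat length (PFD onset model only).
#' @param trajectories data.frame with columns `time_years`, `mean_delta`,
#'   `ci_lower`, `ci_upper`.
#' @param payoffs List with elements `utility` (named PFD, SF1..SF3, SF4_5),
#'   `direct_cost` and `societal_cost` (named SF1..SF5), per year.
#' @param dmt Optional [dmt_scenario()]; `NULL` means natural history.
#' @param pin_hd List of PIN_HD inputs (`tms`, `sdmt`, `coefficients`);
#'   coefficients are configuration, not packaged constants.
#' @param sf5_terminal_cost If TRUE, the annual SF5 cost is charged once to
#'   the mass newly reaching TFC 0 in each cycle. Default FALSE (the
#'   published stage 4–5 results are consistent with no terminal charge).
#' @return An object of class `hd_parameters`.
#' @export
#' @examples
#' p <- hd_parameters("SF1")
#' p$trajectories
hd_parameters <- function(population = c("SF1", "SF2", "PFD"),
                          start_age = NULL, max_age = NULL,
                          discount_rate = NULL, start_tfc = NULL,
                          cag_repeats = NULL, trajectories = NULL,
                          payoffs = NULL, dmt = NULL, pin_hd = NULL,
                          sf5_terminal_cost = FALSE) {
  population <- match.arg(population)
  reg <- table1_base_case()
  traj_pop <- if (population == "PFD") "SF1" else population
  ps <- structure(list(
    population = population,
    start_age = start_age %||% reg$general$start_age,
    max_age = max_age %||% reg$general$max_age,
    discount_rate = discount_rate %||% reg$general$discount_rate,
    start_tfc = start_tfc %||%
      (if (population == "PFD") reg$pfd$tfc else reg$trajectories[[traj_pop]]$start_tfc),
    cag_repeats = cag_repeats %||% reg$pfd$cag_repeats,
    trajectories = trajectories %||% trajectory_df(reg$trajectories[[traj_pop]]),
    payoffs = payoffs %||% default_payoffs(reg),
    dmt = dmt,
    pin_hd = pin_hd %||% list(tms = reg$pfd$tms, sdmt = reg$pfd$sdmt,
                              coefficients = NULL),
    sf5_terminal_cost = isTRUE(sf5_terminal_cost)
  ), class = "hd_parameters")
  validate_parameters(ps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_parameters <- function(ps) {
  fail <- function(...) stop("invalid parameter set: ", sprintf(...), call. = FALSE)
  if (ps$discount_rate < 0 || ps$discount_rate >= 1)
    fail("discount_rate %.3g outside [0, 1)", ps$discount_rate)
  if (ps$start_age >= ps$max_age) fail("start_age must be below max_age")
  rng <- switch(ps$population, PFD = 13L, SF1 = 11:13, SF2 = 7:10)
  if (!ps$start_tfc %in% rng)
    fail("start_tfc %d outside the %s range (%s)", ps$start_tfc,
         ps$population, paste(range(rng), collapse = "-"))
  u <- ps$payoffs$utility
  need_u <- c("PFD", "SF1", "SF2", "SF3", "SF4_5")
  if (!all(need_u %in% names(u))) fail("missing utility for %s",
      paste(setdiff(need_u, names(u)), collapse = ", "))
  if (any(u < 0 | u > 1)) fail("utilities must lie in [0, 1]")
  for (cc in c("direct_cost", "societal_cost")) {
    co <- ps$payoffs[[cc]]
    need_c <- paste0("SF", 1:5)
    if (!all(need_c %in% names(co))) fail("missing %s for %s", cc,
        paste(setdiff(need_c, names(co)), collapse = ", "))
    if (any(co < 0)) fail("%s must be non-negative", cc)
  }
  tr <- ps$trajectories
  if (!all(c("time_years", "mean_delta") %in% names(tr)))
    fail("trajectories need columns time_years, mean_delta")
  if (!is.null(ps$dmt)) {
    if (ps$dmt$delay_years < 0) fail("dmt delay_years must be >= 0")
    if (ps$dmt$rate_ratio <= 0 || ps$dmt$rate_ratio > 1)
      fail("dmt rate_ratio must lie in (0, 1]")
  }
  ps
}

#' Load a parameter set from a configuration document
#'
#' Accepts a named list or a path to a JSON file whose keys mirror the
#' [hd_parameters()] arguments (snake_case). Unspecified keys take the
#' packaged base-case values. Payoff overrides may be partial: e.g.
#' `list(payoffs = list(utility = c(SF1 = 0.8)))` replaces only that entry.
#'
#' @param config Named list or JSON file path; `NULL` or empty means all
#'   defaults.
#' @param population Population used when the document does not name one.
#' @return An `hd_parameters` object.
#' @export
#' @examples
#' load_parameters(list(discount_rate = 0), population = "SF1")
load_parameters <- function(config = NULL, population = "SF1") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- config %||% list()
  if (!is.list(config)) stop("configuration must be a named list or JSON path")
  known <- c("population", "start_age", "max_age", "discount_rate",
             "start_tfc", "cag_repeats", "trajectories", "payoffs", "dmt",
             "pin_hd", "sf5_terminal_cost")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  pop <- config$population %||% population
  base <- hd_parameters(pop)
  merged <- base
  for (f in setdiff(known, c("population", "payoffs", "dmt"))) {
    if (!is.null(config[[f]])) merged[[f]] <- config[[f]]
  }
  if (!is.null(config$payoffs)) {
    for (slot in names(config$payoffs)) {
      ov <- unlist(config$payoffs[[slot]])
      merged$payoffs[[slot]][names(ov)] <- ov
    }
  }
  if (!is.null(config$dmt))
    merged$dmt <- dmt_scenario(delay_years = config$dmt$delay_years %||% 0,
                               rate_ratio = config$dmt$rate_ratio %||% 1)
  merged$trajectories <- as.data.frame(merged$trajectories)
  merged$sf5_terminal_cost <- isTRUE(merged$sf5_terminal_cost)
  validate_parameters(merged)
}

#' @export
print.hd_parameters <- function(x, ...) {
  cat(sprintf("<hd_parameters> %s cohort, age %g-%g, start TFC %d, discount %.1f%%\n",
              x$population, x$start_age, x$max_age, x$start_tfc,
              100 * x$discount_rate))
  if (!is.null(x$dmt))
    cat(sprintf("  DMT: delay %.2g y, rate ratio %.2f\n",
                x$dmt$delay_years, x$dmt$rate_ratio))
  invisible(x)
}
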