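# Uncertainty analysis: probabilistic sensitivity analysis with correlated
# trajectory draws, empirical credible ranges, and one-way (tornado)
# sensitivity analysis at +/- a fixed fraction.

#' Probabilistic-analysis specification
#'
#' Binds each varied model input to a sampling distribution. The default
#' registry follows the packaged base case: the 12-month TFC delta is
#' normal (from its 95% CI); the 36-month delta is perfectly correlated
#' (scaled by the same draw); utilities are beta and costs log-normal, all
#' by method of moments from their printed 95% intervals.
#'
#' @param n_simulations Number of simulations (default 5000).
#' @param seed Integer RNG seed.
#' @param registry Named list of `hd_dist_spec` (see
#'   [default_distribution_registry()]).
#' @param truncate_ci If TRUE, trajectory-delta draws are rejected outside
#'   the reported 95% CI (default FALSE).
#' @return An object of class `hd_psa_spec`.
#' @export
psa_spec <- function(n_simulations = 5000L, seed = 1L, registry = NULL,
                     truncate_ci = FALSE) {
  if (n_simulations < 1) stop("n_simulations must be >= 1")
  structure(list(n_simulations = as.integer(n_simulations),
                 seed = as.integer(seed),
                 registry = registry %||% default_distribution_registry(),
                 truncate_ci = isTRUE(truncate_ci)),
            class = "hd_psa_spec")
}

#' Default sampling-distribution registry from the packaged base case
#'
#' @param population Population whose 12-month trajectory delta is varied.
#' @param zero_variance If TRUE, every entry is a point mass at its base
#'   value (useful for degeneracy checks).
#' @return Named list of `hd_dist_spec`: `tfc_delta_12mo`, `utility_*`,
#'   `direct_cost_*`, `societal_cost_*`.
#' @export
default_distribution_registry <- function(population = "SF1",
                                          zero_variance = FALSE) {
  reg <- table1_base_case()
  traj_pop <- if (population == "PFD") "SF1" else population
  d12 <- reg$trajectories[[traj_pop]]$delta_12mo
  mk <- function(ctor, v) {
    if (zero_variance) new_dist_spec("point", v[1]) else ctor(v[1], v[2], v[3])
  }
  out <- list(tfc_delta_12mo = mk(normal_from_mean_bounds, d12))
  for (s in names(reg$utility))
    out[[paste0("utility_", s)]] <- mk(beta_from_mean_bounds, reg$utility[[s]])
  for (s in names(reg$direct_cost))
    out[[paste0("direct_cost_", s)]] <- mk(lognormal_from_mean_bounds,
                                           reg$direct_cost[[s]])
  for (s in names(reg$societal_cost))
    out[[paste0("societal_cost_", s)]] <- mk(lognormal_from_mean_bounds,
                                             reg$societal_cost[[s]])
  out
}

# per-draw RNG seed kept inside 32-bit integer range
draw_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
}

#' Draw one parameter set for a probabilistic simulation
#'
#' Deterministic in (spec$seed, simulation_index). The 12-month trajectory
#' delta is drawn from its normal spec; the 36-month delta is scaled by
#' the same relative draw (perfect correlation), and downstream the
#' progression regression is re-fit from the drawn deltas, so the
#' transition probability varies with the regression rather than being
#' sampled directly. Utilities and costs are drawn from their beta /
#' log-normal specs.
#'
#' @param params Base-case [hd_parameters()].
#' @param spec An [psa_spec()].
#' @param simulation_index 1-based simulation number.
#' @return An `hd_parameters` draw.
#' @export
sample_parameters <- function(params, spec, simulation_index) {
  stopifnot(inherits(spec, "hd_psa_spec"))
  set.seed(draw_seed(spec$seed, simulation_index))
  reg <- spec$registry
  draw <- params

  d12_spec <- reg$tfc_delta_12mo
  base12 <- params$trajectories$mean_delta[params$trajectories$time_years == 1]
  base36 <- params$trajectories$mean_delta[params$trajectories$time_years == 3]
  d12 <- dist_sample(d12_spec)
  if (spec$truncate_ci && d12_spec$family == "normal" && d12_spec$sd > 0) {
    lo <- params$trajectories$ci_lower[params$trajectories$time_years == 1]
    hi <- params$trajectories$ci_upper[params$trajectories$time_years == 1]
    if (is.finite(lo) && is.finite(hi)) {
      while (d12 < lo || d12 > hi) d12 <- dist_sample(d12_spec)
    }
  }
  scale <- if (base12 != 0) d12 / base12 else 1
  draw$trajectories$mean_delta[params$trajectories$time_years == 1] <- d12
  draw$trajectories$mean_delta[params$trajectories$time_years == 3] <-
    base36 * scale

  for (s in names(params$payoffs$utility)) {
    key <- paste0("utility_", s)
    if (!is.null(reg[[key]]))
      draw$payoffs$utility[s] <- min(1, dist_sample(reg[[key]]))
  }
  for (cc in c("direct_cost", "societal_cost")) {
    for (s in names(params$payoffs[[cc]])) {
      key <- paste0(cc, "_", s)
      if (!is.null(reg[[key]]))
        draw$payoffs[[cc]][s] <- dist_sample(reg[[key]])
    }
  }
  draw
}

#' Empirical 95% credible range
#'
#' 2.5th and 97.5th percentiles with linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param samples Numeric vector (length >= 2 unless constant).
#' @param level Interval mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' credible_range(1:1000)
credible_range <- function(samples, level = 0.95) {
  if (!length(samples)) stop("credible_range: empty sample vector")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

psa_record <- function(out) {
  c(life_years_disc = unname(out$life_years["discounted"]),
    life_years_undisc = unname(out$life_years["undiscounted"]),
    qalys_disc = unname(out$qalys["discounted"]),
    qalys_undisc = unname(out$qalys["undiscounted"]),
    cost_total_disc = unname(out$cost_total["discounted"]),
    cost_total_undisc = unname(out$cost_total["undiscounted"]),
    cost_direct_disc = unname(out$cost_direct["discounted"]),
    cost_societal_disc = unname(out$cost_societal["discounted"]))
}

#' Run a probabilistic sensitivity analysis
#'
#' Repeats the full model evaluation over `spec$n_simulations` parameter
#' draws (optionally as treated-vs-natural increments under a scenario)
#' and summarizes each scalar output by its empirical 95% credible range.
#' Simulations that fail validation are recorded with `NA` outputs and
#' surfaced in the result, never silently dropped.
#'
#' @param params Base-case [hd_parameters()].
#' @param spec An [psa_spec()].
#' @param life_table An [hd_life_table()].
#' @param scenario Optional `hd_dmt_scenario` or library name; when given,
#'   per-simulation records are incremental (treated minus natural, same
#'   draw).
#' @param schedule Onset schedule for PFD populations.
#' @return An `hd_psa_results`: `simulations` (data.frame, one row per
#'   simulation), `summary` (base case, mean, credible bounds per output),
#'   `failures` (indices), `spec`.
#' @export
run_psa <- function(params, spec = psa_spec(), life_table = hd_life_table(),
                    scenario = NULL, schedule = NULL) {
  stopifnot(inherits(spec, "hd_psa_spec"))
  if (is.character(scenario)) scenario <- scenario_library(scenario)
  if (params$population == "PFD") schedule <- schedule %||% default_onset_schedule(params)
  eval_one <- function(ps) {
    if (is.null(scenario)) {
      psa_record(evaluate_model(ps, life_table, schedule))
    } else {
      nat <- ps; nat$dmt <- NULL
      trt <- ps; trt$dmt <- scenario
      psa_record(incremental_outcomes(
        evaluate_model(trt, life_table, schedule),
        evaluate_model(nat, life_table, schedule)))
    }
  }
  base_rec <- eval_one(params)
  n <- spec$n_simulations
  recs <- matrix(NA_real_, n, length(base_rec),
                 dimnames = list(NULL, names(base_rec)))
  failures <- integer(0)
  for (i in seq_len(n)) {
    draw <- try(sample_parameters(params, spec, i), silent = TRUE)
    rec <- if (inherits(draw, "try-error")) draw else
      try(eval_one(draw), silent = TRUE)
    if (inherits(rec, "try-error")) {
      failures <- c(failures, i)
    } else {
      recs[i, ] <- rec
    }
  }
  sims <- as.data.frame(recs)
  ok <- stats::complete.cases(sims)
  summ <- do.call(rbind, lapply(names(sims), function(v) {
    cr <- if (any(ok)) credible_range(sims[[v]][ok]) else
      c(lower = NA_real_, upper = NA_real_)
    data.frame(output = v, base_case = unname(base_rec[v]),
               mean = if (any(ok)) mean(sims[[v]][ok]) else NA_real_,
               cr_lower = cr[["lower"]], cr_upper = cr[["upper"]])
  }))
  structure(list(simulations = sims, summary = summ, failures = failures,
                 population = params$population,
                 scenario = if (is.null(scenario)) NULL else scenario$name,
                 spec = spec),
            class = "hd_psa_results")
}

#' @export
print.hd_psa_results <- function(x, ...) {
  cat(sprintf("<hd_psa_results> %s population%s, %d simulations (%d failed)\n",
              x$population,
              if (is.null(x$scenario)) "" else paste0(", scenario ", x$scenario),
              nrow(x$simulations), length(x$failures)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

## ---------------------------------------------------------------------------
## One-way (tornado) sensitivity analysis

owsa_parameter_list <- function(params, scenario = NULL) {
  out <- list(
    tfc_delta_12mo = list(
      get = function(p) p$trajectories$mean_delta[p$trajectories$time_years == 1],
      set = function(p, v) {
        base12 <- p$trajectories$mean_delta[p$trajectories$time_years == 1]
        sc <- v / base12
        p$trajectories$mean_delta[p$trajectories$time_years == 1] <- v
        p$trajectories$mean_delta[p$trajectories$time_years == 3] <-
          p$trajectories$mean_delta[p$trajectories$time_years == 3] * sc
        p
      }),
    discount_rate = list(
      get = function(p) p$discount_rate,
      set = function(p, v) { p$discount_rate <- v; p })
  )
  for (s in names(params$payoffs$utility)) local({
    s <- s
    out[[paste0("utility_", s)]] <<- list(
      get = function(p) p$payoffs$utility[[s]],
      set = function(p, v) { p$payoffs$utility[s] <- min(1, v); p })
  })
  for (cc in c("direct_cost", "societal_cost"))
    for (s in names(params$payoffs[[cc]])) local({
      cc <- cc; s <- s
      out[[paste0(cc, "_", s)]] <<- list(
        get = function(p) p$payoffs[[cc]][[s]],
        set = function(p, v) { p$payoffs[[cc]][s] <- max(0, v); p })
    })
  if (!is.null(scenario)) {
    out$rate_ratio <- list(
      get = function(p) scenario$rate_ratio,
      set = function(p, v) v,     # handled by caller (scenario field)
      scenario_field = "rate_ratio")
    out$delay_years <- list(
      get = function(p) scenario$delay_years,
      set = function(p, v) v,
      scenario_field = "delay_years")
  }
  out
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies each model input one at a time to base*(1 - fraction) and
#' base*(1 + fraction) (utilities capped at 1; rate ratio capped at 1),
#' re-runs the model, and ranks parameters by the absolute width of the
#' outcome swing. With a scenario, the outcome is incremental versus
#' natural history and the scenario's delay and rate ratio are varied too.
#'
#' @param params Base-case [hd_parameters()].
#' @param life_table An [hd_life_table()].
#' @param fraction Relative variation (default 0.25).
#' @param scenario Optional `hd_dmt_scenario` or library name.
#' @param outcome Output to track: one of the column names of
#'   [run_psa()] records (default "qalys_disc").
#' @param schedule Onset schedule for PFD populations.
#' @return An `hd_tornado_table` data.frame: `parameter`, `base_value`,
#'   `low_value`, `high_value`, `outcome_low`, `outcome_high`, `width`,
#'   sorted by decreasing `|width|`.
#' @export
run_owsa <- function(params, life_table = hd_life_table(), fraction = 0.25,
                     scenario = NULL, outcome = "qalys_disc",
                     schedule = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (is.character(scenario)) scenario <- scenario_library(scenario)
  if (params$population == "PFD") schedule <- schedule %||% default_onset_schedule(params)
  eval_outcome <- function(ps, scen) {
    rec <- if (is.null(scen)) {
      psa_record(evaluate_model(ps, life_table, schedule))
    } else {
      nat <- ps; nat$dmt <- NULL
      trt <- ps; trt$dmt <- scen
      psa_record(incremental_outcomes(
        evaluate_model(trt, life_table, schedule),
        evaluate_model(nat, life_table, schedule)))
    }
    rec[[outcome]]
  }
  plist <- owsa_parameter_list(params, scenario)
  rows <- lapply(names(plist), function(nm) {
    h <- plist[[nm]]
    base <- h$get(params)
    lo <- base * (1 - fraction); hi <- base * (1 + fraction)
    run_at <- function(v) {
      if (!is.null(h$scenario_field)) {
        scen <- scenario
        scen[[h$scenario_field]] <- if (h$scenario_field == "rate_ratio")
          min(1, v) else max(0, v)
        eval_outcome(params, scen)
      } else {
        eval_outcome(h$set(params, v), scenario)
      }
    }
    out_lo <- run_at(lo); out_hi <- run_at(hi)
    data.frame(parameter = nm, base_value = base, low_value = lo,
               high_value = hi, outcome_low = out_lo, outcome_high = out_hi,
               width = out_hi - out_lo)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-abs(tab$width)), ]
  rownames(tab) <- NULL
  class(tab) <- c("hd_tornado_table", class(tab))
  tab
}
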