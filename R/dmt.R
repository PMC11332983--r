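# Hypothetical disease-modifying treatment scenarios and incremental
# outcomes versus natural history.

#' Define a disease-modifying treatment scenario
#'
#' A scenario arrests further functional decline for `delay_years` and
#' multiplies the annual progression probability by `rate_ratio`
#' thereafter. For prefunctional cohorts the delay shifts the onset
#' schedule later; for SF1/SF2 cohorts it zeroes progression during the
#' delay (background mortality still applies). The identity scenario is
#' `(0, 1)`.
#'
#' @param delay_years Non-negative years of arrested progression/onset
#'   (fractional values supported for sensitivity analysis).
#' @param rate_ratio Multiplier in (0, 1] on the progression probability.
#' @param name Optional label.
#' @return An object of class `hd_dmt_scenario`.
#' @export
dmt_scenario <- function(delay_years = 0, rate_ratio = 1, name = NULL) {
  if (delay_years < 0) stop("delay_years must be >= 0")
  if (rate_ratio <= 0 || rate_ratio > 1) stop("rate_ratio must lie in (0, 1]")
  structure(list(delay_years = delay_years, rate_ratio = rate_ratio,
                 name = name), class = "hd_dmt_scenario")
}

#' Packaged treatment scenario library
#'
#' Three efficacy assumptions: A = 3-year delay with a 0.75 rate ratio,
#' B = 2 years / 0.85, C = 1 year / 0.95.
#'
#' @param name Optional scenario name; omit for the full named list.
#' @return An `hd_dmt_scenario`, or a named list of all three.
#' @export
#' @examples
#' scenario_library("A")
scenario_library <- function(name = NULL) {
  lib <- list(A = dmt_scenario(3, 0.75, "A"),
              B = dmt_scenario(2, 0.85, "B"),
              C = dmt_scenario(1, 0.95, "C"))
  if (is.null(name)) return(lib)
  if (!name %in% names(lib))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  lib[[name]]
}

#' Incremental outcomes: treated minus natural history
#'
#' Element-wise differences of every total and by-stage breakdown. Both
#' outcome sets must describe the same population, discount rate and stage
#' structure.
#'
#' @param treated,natural `hd_outcome_set` objects.
#' @return An `hd_incremental_set` with the same shape (differences).
#' @export
incremental_outcomes <- function(treated, natural) {
  stopifnot(inherits(treated, "hd_outcome_set"),
            inherits(natural, "hd_outcome_set"))
  if (treated$population != natural$population)
    stop("population mismatch: ", treated$population, " vs ", natural$population)
  if (abs(treated$discount_rate - natural$discount_rate) > 1e-12)
    stop("discount-rate mismatch between treated and natural outcome sets")
  diff_df <- function(a, b, key) {
    m <- merge(a, b, by = key, suffixes = c("_t", "_n"), sort = FALSE)
    out <- m[key]
    out$discounted <- m$discounted_t - m$discounted_n
    out$undiscounted <- m$undiscounted_t - m$undiscounted_n
    out
  }
  structure(list(
    population = treated$population,
    discount_rate = treated$discount_rate,
    life_years = treated$life_years - natural$life_years,
    qalys = treated$qalys - natural$qalys,
    qalys_by_stage = diff_df(treated$qalys_by_stage, natural$qalys_by_stage, "stage"),
    cost_direct = treated$cost_direct - natural$cost_direct,
    cost_societal = treated$cost_societal - natural$cost_societal,
    cost_total = treated$cost_total - natural$cost_total,
    costs = diff_df(treated$costs, natural$costs, c("category", "stage")),
    median_survival_years = treated$median_survival_years -
      natural$median_survival_years
  ), class = "hd_incremental_set")
}

#' Evaluate a treatment scenario against natural history
#'
#' Runs the model twice — with and without the scenario — on otherwise
#' identical parameters and returns the incremental set.
#'
#' @param params Natural-history [hd_parameters()] (its `dmt` is ignored).
#' @param scenario An `hd_dmt_scenario` or a library name ("A", "B", "C").
#' @param life_table An [hd_life_table()].
#' @param schedule,pfd_delay_mode Passed to [evaluate_model()] for PFD.
#' @return An `hd_incremental_set`.
#' @export
#' @examples
#' evaluate_dmt(hd_parameters("SF1"), "A")
evaluate_dmt <- function(params, scenario, life_table = hd_life_table(),
                         schedule = NULL, pfd_delay_mode = "shift") {
  if (is.character(scenario)) scenario <- scenario_library(scenario)
  stopifnot(inherits(scenario, "hd_dmt_scenario"))
  natural <- params; natural$dmt <- NULL
  treated <- params; treated$dmt <- scenario
  incremental_outcomes(
    evaluate_model(treated, life_table, schedule, pfd_delay_mode),
    evaluate_model(natural, life_table, schedule, pfd_delay_mode)
  )
}

#' @export
print.hd_incremental_set <- function(x, ...) {
  cat(sprintf("<hd_incremental_set> %s population, treated minus natural history\n",
              x$population))
  cat(sprintf("  incremental life years: %+.2f disc / %+.2f undisc\n",
              x$life_years[1], x$life_years[2]))
  cat(sprintf("  incremental QALYs     : %+.2f disc / %+.2f undisc\n",
              x$qalys[1], x$qalys[2]))
  cat(sprintf("  incremental cost      : %+.0f disc / %+.0f undisc (USD)\n",
              x$cost_total[1], x$cost_total[2]))
  invisible(x)
}
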