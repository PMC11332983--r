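# Cohort engine: annual-cycle propagation of occupancy over the live TFC
# states (plus a prefunctional state for PFD cohorts), with competing
# background mortality, and accumulation of discounted/undiscounted life
# years, QALYs and stage-specific costs.

# internal: q_death vector for cycles 1..T (ages start_age .. max_age-1)
lifetable_q <- function(life_table, start_age, max_age) {
  stopifnot(inherits(life_table, "hd_life_table"))
  ages <- start_age:(max_age - 1)
  idx <- match(ages, life_table$age)
  if (anyNA(idx))
    stop("life table does not cover ages ", paste(range(ages[is.na(idx)]),
         collapse = "-"))
  life_table$qx[idx]
}

# internal: propagate a 13-vector of live-TFC occupancy over n cycles.
# start_vec is ordered TFC 13..1; q is length-n background death prob.
# Returns occupancy (n+1 x 13), cumulative dead_hd/dead_bg (n+1), and
# entry_to_death (n, mass newly reaching TFC 0 during each cycle).
propagate_cohort <- function(start_vec, p, q, delay = 0, rate_ratio = 1) {
  n <- length(q)
  occ <- matrix(0, n + 1, 13)
  occ[1, ] <- start_vec
  dead_hd <- dead_bg <- numeric(n + 1)
  entry <- numeric(n)
  v <- start_vec
  for (t in seq_len(n)) {
    ps <- effective_progression(p, t, delay, rate_ratio)
    surv <- v * (1 - q[t])
    down <- surv * ps
    nv <- surv - down
    nv[2:13] <- nv[2:13] + down[1:12]
    entry[t] <- down[13]
    dead_bg[t + 1] <- dead_bg[t] + sum(v) * q[t]
    dead_hd[t + 1] <- dead_hd[t] + down[13]
    v <- nv
    occ[t + 1, ] <- v
  }
  list(occupancy = occ, dead_hd = dead_hd, dead_bg = dead_bg,
       entry_to_death = entry)
}

new_trace <- function(params, occupancy, dead_hd, dead_bg, entry_to_death) {
  T <- nrow(occupancy) - 1L
  structure(list(
    population = params$population,
    start_age = params$start_age,
    ages = params$start_age + 0:T,
    occupancy = occupancy,            # (T+1) x states, cycle-start mass
    dead_hd = dead_hd, dead_bg = dead_bg,
    entry_to_death = entry_to_death
  ), class = "hd_trace")
}

#' Run a natural-history or treated cohort (SF1/SF2 populations)
#'
#' Starts 100% of the cohort in `params$start_tfc` and propagates it
#' annually until `max_age`: background death first (age-specific life
#' table), then one-state TFC decline among survivors at the trajectory-
#' derived probability. A treatment scenario arrests progression for its
#' delay and multiplies the probability by its rate ratio thereafter.
#'
#' @param params An [hd_parameters()] with population "SF1" or "SF2".
#' @param life_table An [hd_life_table()] covering the modeled ages.
#' @return An `hd_trace`: cycle-start occupancy over states
#'   `tfc13..tfc1` plus cumulative `dead_hd` / `dead_bg` and the per-cycle
#'   mass newly reaching TFC 0.
#' @export
#' @examples
#' tr <- run_cohort(hd_parameters("SF1"), hd_life_table())
#' median_survival(tr)
run_cohort <- function(params, life_table = hd_life_table()) {
  if (!params$population %in% c("SF1", "SF2"))
    stop("run_cohort is for SF1/SF2 populations; use run_pfd_cohort for PFD")
  p <- progression_model(params)$annual_transition_probability
  q <- lifetable_q(life_table, params$start_age, params$max_age)
  start <- numeric(13)
  start[14 - params$start_tfc] <- 1          # index 1 = TFC 13
  delay <- if (is.null(params$dmt)) 0 else params$dmt$delay_years
  rr <- if (is.null(params$dmt)) 1 else params$dmt$rate_ratio
  pr <- propagate_cohort(start, p, q, delay, rr)
  tr <- new_trace(params, cbind(pfd = 0, pr$occupancy), pr$dead_hd,
                  pr$dead_bg, pr$entry_to_death)
  colnames(tr$occupancy) <- c("pfd", paste0("tfc", tfc_live_states()))
  tr
}

#' Run a prefunctional-decline cohort pooled over onset subcohorts
#'
#' Each subcohort k (weight w(k) from the onset schedule) remains in the
#' prefunctional state, exposed to background mortality only, for k full
#' years; its survivors then enter TFC 13 and progress at the SF1 rate.
#' The pooled trace is the weight-averaged mixture of all subcohorts plus
#' the residual never-onset subcohort. Under a treatment scenario the
#' schedule is shifted later by the delay (mass pushed past the horizon
#' never onsets) and the rate ratio applies post-onset; `pause` mode
#' instead keeps the schedule and arrests progression within subcohorts.
#'
#' @param params An [hd_parameters()] with population "PFD".
#' @param schedule An [onset_schedule()] whose length equals the horizon.
#' @param life_table An [hd_life_table()].
#' @param pfd_delay_mode "shift" (default) or "pause" handling of the DMT
#'   delay for this population.
#' @return An `hd_trace` with states `pfd`, `tfc13..tfc1`.
#' @export
run_pfd_cohort <- function(params, schedule, life_table = hd_life_table(),
                           pfd_delay_mode = c("shift", "pause")) {
  if (params$population != "PFD") stop("run_pfd_cohort requires population PFD")
  pfd_delay_mode <- match.arg(pfd_delay_mode)
  T <- params$max_age - params$start_age
  if (length(schedule$weights) != T)
    stop("onset schedule length ", length(schedule$weights),
         " does not match model horizon ", T)
  p <- progression_model(params)$annual_transition_probability
  q <- lifetable_q(life_table, params$start_age, params$max_age)
  delay <- if (is.null(params$dmt)) 0 else params$dmt$delay_years
  rr <- if (is.null(params$dmt)) 1 else params$dmt$rate_ratio
  sub_delay <- 0
  if (delay > 0) {
    if (pfd_delay_mode == "shift") schedule <- shift_onset_schedule(schedule, delay)
    else sub_delay <- delay             # pause: arrest within each subcohort
  }
  w <- schedule$weights
  pre_surv <- c(1, cumprod(1 - q))      # survival to cycle-start k in PFD state

  occ <- matrix(0, T + 1, 14,
                dimnames = list(NULL, c("pfd", paste0("tfc", tfc_live_states()))))
  dead_hd <- dead_bg <- numeric(T + 1)
  entry <- numeric(T)

  add_pre_onset <- function(weight, k) {
    # PFD occupancy for cycles 0..k-1 and background deaths accrued there
    if (weight == 0) return()
    if (k > 0) {
      occ[1:k, "pfd"] <<- occ[1:k, "pfd"] + weight * pre_surv[1:k]
      d <- weight * cumsum(pre_surv[1:k] * q[1:k])
      dead_bg[2:(k + 1)] <<- dead_bg[2:(k + 1)] + d
      if (k < T) dead_bg[(k + 2):(T + 1)] <<- dead_bg[(k + 2):(T + 1)] + d[k]
      else NULL
    }
  }

  for (k in 0:(T - 1)) {
    wk <- w[k + 1]
    if (wk == 0) next
    add_pre_onset(wk, k)
    start <- c(wk * pre_surv[k + 1], numeric(12))
    pr <- propagate_cohort(start, p, q[(k + 1):T], sub_delay, rr)
    rows <- (k + 1):(T + 1)
    occ[rows, 2:14] <- occ[rows, 2:14] + pr$occupancy
    dead_hd[rows] <- dead_hd[rows] + pr$dead_hd
    dead_bg[rows] <- dead_bg[rows] + pr$dead_bg
    entry[(k + 1):T] <- entry[(k + 1):T] + pr$entry_to_death
  }
  resid <- schedule$residual_weight
  if (resid > 0) {                      # never-onset: PFD for the whole horizon
    occ[, "pfd"] <- occ[, "pfd"] + resid * pre_surv
    dead_bg <- dead_bg + resid * c(0, cumsum(pre_surv[1:T] * q))
  }
  new_trace(params, occ, dead_hd, dead_bg, entry)
}

#' Survival curve of a trace
#' @param trace An `hd_trace`.
#' @return Numeric vector S(t), t = 0..T (fraction alive at cycle start).
#' @export
survival_curve <- function(trace) {
  stopifnot(inherits(trace, "hd_trace"))
  1 - trace$dead_hd - trace$dead_bg
}

#' Median survival with linear interpolation
#'
#' First crossing of S(t) = 0.5 on the annual grid, linearly interpolated;
#' `Inf` if survival never falls below 0.5 before the horizon.
#'
#' @param trace An `hd_trace` (or a bare numeric survival curve).
#' @return Years from model entry (numeric scalar).
#' @export
median_survival <- function(trace) {
  S <- if (inherits(trace, "hd_trace")) survival_curve(trace) else trace
  if (abs(S[1] - 1) > 1e-9) stop("survival curve must start at 1")
  i <- which(S < 0.5)[1]
  if (is.na(i)) return(Inf)
  t0 <- i - 2L
  t0 + (S[i - 1] - 0.5) / (S[i - 1] - S[i])
}

#' @export
print.hd_trace <- function(x, ...) {
  S <- survival_curve(x)
  cat(sprintf("<hd_trace> %s cohort, ages %g-%g, %d cycles; S(end) = %.4f, median survival %.2f y\n",
              x$population, min(x$ages), max(x$ages), length(x$ages) - 1,
              S[length(S)], median_survival(x)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Outcome accumulation

stage_of_column <- function(cols) {
  tfc <- as.integer(sub("^tfc", "", cols[cols != "pfd"]))
  c(if ("pfd" %in% cols) "PFD", sf_stage(tfc))
}

#' Accumulate life years, QALYs and costs over a cohort trace
#'
#' Per cycle t = 0..T-1, the cycle-start occupancy accrues one year of the
#' state's annual payoff, discounted by (1+d)^(-t) (t = 0 undiscounted; no
#' half-cycle correction). TFC states take their Shoulson–Fahn stage's
#' utility and costs; the prefunctional state takes the population-norm
#' utility and zero HD-attributable cost. Optionally the annual SF5 cost is
#' charged once to mass newly reaching TFC 0, discounted at its entry cycle.
#'
#' @param trace An `hd_trace`.
#' @param payoffs Stage payoffs (see [hd_parameters()]); defaults to the
#'   packaged base case.
#' @param discount_rate Annual discount fraction.
#' @param sf5_terminal_cost Charge the SF5 annual cost once on entry to
#'   TFC 0 (default FALSE; see the package vignette).
#' @return An `hd_outcome_set`: totals and by-stage breakdowns, discounted
#'   and undiscounted, plus median survival.
#' @export
#' @examples
#' tr <- run_cohort(hd_parameters("SF1"), hd_life_table())
#' accumulate_outcomes(tr, discount_rate = 0.03)
accumulate_outcomes <- function(trace, payoffs = default_payoffs(),
                                discount_rate = 0.03,
                                sf5_terminal_cost = FALSE) {
  stopifnot(inherits(trace, "hd_trace"))
  T <- nrow(trace$occupancy) - 1L
  occ <- trace$occupancy[1:T, , drop = FALSE]
  disc <- (1 + discount_rate)^-(0:(T - 1))
  cols <- colnames(trace$occupancy)
  stages <- stage_of_column(cols)

  u_key <- ifelse(stages %in% c("SF4", "SF5"), "SF4_5", stages)
  u <- payoffs$utility[u_key]
  c_key <- stages                            # PFD carries no HD cost
  dc <- ifelse(stages == "PFD", 0, payoffs$direct_cost[c_key])
  sc <- ifelse(stages == "PFD", 0, payoffs$societal_cost[c_key])

  per_state <- function(w) {                 # per-state disc/undisc totals
    cbind(discounted = colSums(occ * disc) * w, undiscounted = colSums(occ) * w)
  }
  ly <- per_state(rep(1, length(cols)))
  qa <- per_state(u)
  cd <- per_state(dc)
  cs <- per_state(sc)

  by_stage <- function(m) {
    agg <- rowsum(m, stages)
    data.frame(stage = rownames(agg), discounted = agg[, 1],
               undiscounted = agg[, 2], row.names = NULL)
  }
  term <- c(discounted = 0, undiscounted = 0)
  term_soc <- term
  if (sf5_terminal_cost) {
    e <- trace$entry_to_death
    df <- (1 + discount_rate)^-(1:T)         # entry counted at next cycle start
    sf5d <- unname(payoffs$direct_cost["SF5"])
    sf5s <- unname(payoffs$societal_cost["SF5"])
    term <- c(discounted = sum(e * df) * sf5d, undiscounted = sum(e) * sf5d)
    term_soc <- c(discounted = sum(e * df) * sf5s, undiscounted = sum(e) * sf5s)
  }

  qalys_by_stage <- by_stage(qa)
  direct_by_stage <- by_stage(cd)
  societal_by_stage <- by_stage(cs)
  if (sf5_terminal_cost) {
    sf5row <- function(v) data.frame(stage = "SF5", discounted = v[["discounted"]],
                                     undiscounted = v[["undiscounted"]])
    direct_by_stage <- rbind(direct_by_stage, sf5row(term))
    societal_by_stage <- rbind(societal_by_stage, sf5row(term_soc))
  }

  tot <- function(df) c(discounted = sum(df$discounted),
                        undiscounted = sum(df$undiscounted))
  costs <- rbind(
    data.frame(category = "direct", direct_by_stage),
    data.frame(category = "societal", societal_by_stage)
  )
  structure(list(
    population = trace$population,
    discount_rate = discount_rate,
    life_years = c(discounted = sum(ly[, 1]), undiscounted = sum(ly[, 2])),
    qalys = tot(qalys_by_stage),
    qalys_by_stage = qalys_by_stage,
    cost_direct = tot(direct_by_stage),
    cost_societal = tot(societal_by_stage),
    cost_total = tot(direct_by_stage) + tot(societal_by_stage),
    costs = costs,
    median_survival_years = median_survival(trace)
  ), class = "hd_outcome_set")
}

#' End-to-end evaluation of a parameter set
#'
#' Runs the appropriate cohort engine for the population (SF1/SF2 direct;
#' PFD pooled over its onset schedule) and accumulates outcomes.
#'
#' @param params An [hd_parameters()].
#' @param life_table An [hd_life_table()].
#' @param schedule Onset schedule (PFD only); defaults to the packaged
#'   synthetic staging-system curves at `params$cag_repeats`.
#' @param pfd_delay_mode See [run_pfd_cohort()].
#' @return An `hd_outcome_set`.
#' @export
evaluate_model <- function(params, life_table = hd_life_table(),
                           schedule = NULL, pfd_delay_mode = "shift") {
  trace <- if (params$population == "PFD") {
    schedule <- schedule %||% default_onset_schedule(params)
    run_pfd_cohort(params, schedule, life_table, pfd_delay_mode)
  } else {
    run_cohort(params, life_table)
  }
  accumulate_outcomes(trace, params$payoffs, params$discount_rate,
                      params$sf5_terminal_cost)
}

#' Onset schedule from the packaged synthetic staging-system fixture
#' @param params An `hd_parameters` (uses `cag_repeats` and the age window).
#' @return An `hd_onset_schedule`.
#' @export
default_onset_schedule <- function(params) {
  pts <- read_onset_points()
  pts <- pts[pts$cag == params$cag_repeats, ]
  if (!nrow(pts))
    stop("packaged onset fixture has no CAG ", params$cag_repeats, " stratum")
  onset_schedule(fit_onset_curve(pts), params$start_age, params$max_age)
}

#' @export
print.hd_outcome_set <- function(x, ...) {
  cat(sprintf("<hd_outcome_set> %s population (discount %.1f%%)\n",
              x$population, 100 * x$discount_rate))
  cat(sprintf("  life years : %8.2f discounted / %8.2f undiscounted\n",
              x$life_years[1], x$life_years[2]))
  cat(sprintf("  QALYs      : %8.2f discounted / %8.2f undiscounted\n",
              x$qalys[1], x$qalys[2]))
  cat(sprintf("  total cost : $%s discounted / $%s undiscounted\n",
              format(round(x$cost_total[1]), big.mark = ","),
              format(round(x$cost_total[2]), big.mark = ",")))
  cat(sprintf("  median survival: %.1f years\n", x$median_survival_years))
  invisible(x)
}
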