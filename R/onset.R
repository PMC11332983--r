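# Onset of functional decline for prefunctional cohorts: parametric
# (logistic) fits to cumulative stage-3 probabilities by age and CAG,
# conversion to a renormalized annual onset schedule up to the model
# horizon, and the PIN_HD composite as an alternative onset driver.

logistic_cdf <- function(age, location, scale) {
  stats::plogis(age, location = location, scale = scale)
}

#' Fit a logistic onset curve to cumulative probabilities
#'
#' Least-squares fit of F(a) = 1 / (1 + exp(-(a - location)/scale)) to
#' observed (age, cumulative probability) points, one curve per CAG
#' stratum. Points generated from a logistic curve are recovered exactly
#' (to optimizer tolerance); higher-CAG strata fit earlier locations.
#'
#' @param points data.frame with columns `age` and `cumulative_probability`
#'   (a `cag` column, if present, must be constant).
#' @param cag CAG repeat length recorded on the result (informational).
#' @return An object of class `hd_onset_curve`: list with `cag`, `family`,
#'   `location` (years), `scale` (years), `sse`.
#' @export
#' @examples
#' pts <- data.frame(age = seq(30, 90, 5),
#'                   cumulative_probability = plogis(seq(30, 90, 5), 55, 8))
#' fit_onset_curve(pts, cag = 40)
fit_onset_curve <- function(points, cag = NA_integer_) {
  if ("cag" %in% names(points)) {
    stopifnot(length(unique(points$cag)) == 1)
    if (is.na(cag)) cag <- points$cag[1]
  }
  a <- points$age
  p <- points$cumulative_probability
  if (length(a) < 3) stop("need at least 3 points to fit an onset curve")
  if (any(p < 0 | p > 1)) stop("cumulative probabilities must lie in [0, 1]")
  if (is.unsorted(a, strictly = TRUE)) stop("ages must be strictly increasing")
  if (any(diff(p) < -1e-6))
    stop("cumulative probabilities decrease beyond tolerance; not a CDF")

  # init: age at p = 0.5 by interpolation; scale from logit-linear slope
  loc0 <- if (any(p >= 0.5) && any(p <= 0.5)) {
    stats::approx(p, a, xout = 0.5, ties = "ordered")$y
  } else mean(a)
  inner <- p > 0.02 & p < 0.98
  sc0 <- if (sum(inner) >= 2) {
    fit <- stats::lm(stats::qlogis(p[inner]) ~ a[inner])
    1 / max(abs(stats::coef(fit)[2]), 1e-3)
  } else diff(range(a)) / 6
  obj <- function(th) sum((logistic_cdf(a, th[1], exp(th[2])) - p)^2)
  opt <- stats::optim(c(loc0 %||% mean(a), log(sc0)), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0)
    stop("onset-curve fit failed to converge (code ", opt$convergence, ")")
  structure(list(cag = cag, family = "logistic",
                 location = opt$par[1], scale = exp(opt$par[2]),
                 sse = opt$value),
            class = "hd_onset_curve")
}

#' Evaluate an onset curve
#' @param curve An `hd_onset_curve`, or any function age -> cumulative
#'   probability (pluggable family).
#' @param age Ages (years).
#' @return Cumulative probability of onset by each age.
#' @export
onset_cdf <- function(curve, age) {
  if (is.function(curve)) return(curve(age))
  stopifnot(inherits(curve, "hd_onset_curve"))
  logistic_cdf(age, curve$location, curve$scale)
}

#' @export
print.hd_onset_curve <- function(x, ...) {
  cat(sprintf("<hd_onset_curve> CAG %s: logistic(location %.2f y, scale %.2f y), sse %.3g\n",
              x$cag, x$location, x$scale, x$sse))
  invisible(x)
}

#' Annual onset schedule from a fitted curve
#'
#' Converts the cumulative curve into per-model-year onset probabilities by
#' truncating to the modeled age window and renormalizing, so the full
#' onset mass between entry and the horizon is allocated across the
#' remaining years: w(t) = (F(a0+t+1) - F(a0+t)) / (F(amax) - F(a0)).
#' Under this renormalization the residual (no-onset) weight is 0 and the
#' weights sum to one.
#'
#' @param curve An `hd_onset_curve` or a CDF function of age.
#' @param start_age,max_age Modeled age window (years, start < max).
#' @return An object of class `hd_onset_schedule`: `start_age`, `weights`
#'   (length `max_age - start_age`, onset in cycle t means entering TFC 13
#'   after t full years in the prefunctional state), `residual_weight`.
#' @export
onset_schedule <- function(curve, start_age = 40, max_age = 100) {
  if (start_age >= max_age) stop("start_age must be below max_age")
  ages <- start_age:max_age
  Fv <- onset_cdf(curve, ages)
  denom <- Fv[length(Fv)] - Fv[1]
  if (denom <= 1e-12)
    stop("degenerate onset curve: flat over the modeled age window")
  w <- diff(Fv) / denom
  new_onset_schedule(start_age, w, residual_weight = 0)
}

new_onset_schedule <- function(start_age, weights, residual_weight = 0) {
  tot <- sum(weights) + residual_weight
  if (any(weights < -1e-12) || abs(tot - 1) > 1e-9)
    stop("onset schedule weights must be non-negative and sum to 1")
  structure(list(start_age = start_age, weights = pmax(weights, 0),
                 residual_weight = residual_weight),
            class = "hd_onset_schedule")
}

#' Shift an onset schedule later (treatment delay)
#'
#' Translates the whole schedule `delay` years later; onset mass pushed
#' beyond the horizon becomes residual (never-onset) weight. Fractional
#' delays split each weight linearly between the two adjacent cycles.
#'
#' @param schedule An `hd_onset_schedule`.
#' @param delay Non-negative delay in years.
#' @return A shifted `hd_onset_schedule`.
#' @export
shift_onset_schedule <- function(schedule, delay) {
  stopifnot(inherits(schedule, "hd_onset_schedule"), delay >= 0)
  if (delay == 0) return(schedule)
  w <- schedule$weights
  n <- length(w)
  d0 <- floor(delay); fr <- delay - d0
  out <- numeric(n)
  for (k in seq_along(w) - 1L) {           # onset cycle k -> k + delay
    tgt <- k + d0
    if (fr == 0) {
      if (tgt < n) out[tgt + 1] <- out[tgt + 1] + w[k + 1]
    } else {
      if (tgt < n) out[tgt + 1] <- out[tgt + 1] + (1 - fr) * w[k + 1]
      if (tgt + 1 < n) out[tgt + 2] <- out[tgt + 2] + fr * w[k + 1]
    }
  }
  new_onset_schedule(schedule$start_age, out,
                     residual_weight = schedule$residual_weight + sum(w) - sum(out))
}

#' @export
print.hd_onset_schedule <- function(x, ...) {
  cat(sprintf("<hd_onset_schedule> start age %g, %d yearly weights (sum %.6f), residual %.4f\n",
              x$start_age, length(x$weights), sum(x$weights), x$residual_weight))
  invisible(x)
}

#' PIN_HD composite prognostic score
#'
#' Normalized weighted composite of the total motor score (TMS), the symbol
#' digit modalities test (SDMT) and the CAG-adjusted age product:
#' `((w_tms * tms + w_sdmt * sdmt + w_cagage * (cag - cag_offset) * age)
#'   - center) / scale`.
#' All coefficients come from configuration; none are packaged, because the
#' published composite's weights are external to this model.
#'
#' @param tms,sdmt,cag,age Subject-level inputs.
#' @param coefficients Named list/vector with `w_tms`, `w_sdmt`, `w_cagage`,
#'   `cag_offset`, `center`, `scale`.
#' @return Numeric score (vectorized over the inputs).
#' @export
#' @examples
#' co <- list(w_tms = 1, w_sdmt = 1, w_cagage = 1,
#'            cag_offset = 0, center = 0, scale = 1)
#' pin_hd_score(2, 50, 40, 40, co)
pin_hd_score <- function(tms, sdmt, cag, age, coefficients) {
  if (is.null(coefficients)) stop("PIN_HD coefficients must be configured")
  co <- as.list(coefficients)
  need <- c("w_tms", "w_sdmt", "w_cagage", "cag_offset", "center", "scale")
  miss <- setdiff(need, names(co))
  if (length(miss)) stop("missing PIN_HD coefficient(s): ",
                         paste(miss, collapse = ", "))
  if (co$scale == 0) stop("PIN_HD scale must be non-zero")
  (co$w_tms * tms + co$w_sdmt * sdmt +
     co$w_cagage * (cag - co$cag_offset) * age - co$center) / co$scale
}

#' Onset schedule from a PIN_HD trajectory
#'
#' Alternative onset driver: the composite is evaluated at each model age
#' (it grows with age through the CAG-age product), mapped to an annual
#' onset hazard by a pluggable link (default: logistic), and the resulting
#' per-year onset probabilities are renormalized over the horizon like the
#' staging-system schedule.
#'
#' @param params An `hd_parameters` with `pin_hd$coefficients` configured.
#' @param link Function score -> annual onset hazard in [0, 1].
#' @return An `hd_onset_schedule`.
#' @export
pin_hd_onset_schedule <- function(params, link = stats::plogis) {
  n <- params$max_age - params$start_age
  ages <- params$start_age + seq_len(n) - 1L
  sc <- pin_hd_score(params$pin_hd$tms, params$pin_hd$sdmt,
                     params$cag_repeats, ages, params$pin_hd$coefficients)
  h <- pmin(pmax(link(sc), 0), 1)
  surv <- cumprod(1 - h)
  w <- h * c(1, surv[-n])                 # P(onset in year t)
  tot <- sum(w)
  if (tot <= 1e-12) stop("PIN_HD link yields no onset mass over the horizon")
  new_onset_schedule(params$start_age, w / tot, residual_weight = 0)
}

#' Fit onset curves for every CAG stratum in a points table
#'
#' @param points data.frame with columns `cag`, `age`,
#'   `cumulative_probability` (e.g. from [read_onset_points()]).
#' @return Named list of `hd_onset_curve`, keyed by CAG.
#' @export
fit_onset_curves <- function(points) {
  out <- lapply(split(points, points$cag), fit_onset_curve)
  names(out) <- names(split(points, points$cag))
  out
}
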