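---
title: "Modeling lifetime Huntington disease outcomes with hdcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling lifetime Huntington disease outcomes with hdcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdcohort)
```

## The model

hdcohort implements a cohort (expected-value) state-transition model of
Huntington disease (HD) functional decline. The health states are the 14
levels of the Total Functional Capacity (TFC) scale; TFC 0 — the sole
state of Shoulson–Fahn stage 5 — is treated as equivalent to death.
Cycles are annual. In each cycle a cohort member either dies of
background causes (age-specific probability from a life table), moves
down exactly one TFC state (probability `p` among survivors), or stays.
Reaching TFC 0 is death from progression. There is no recovery and no
excess HD mortality before TFC 0 beyond the background rates — survival
is driven entirely by the race between progression and secular death.

```{r}
params <- hd_parameters("SF1")
evaluate_model(params, hd_life_table())
```

### The progression rate

`p` is derived from short-horizon trajectory data: ordinary least
squares (with intercept) of mean TFC change from baseline on time, fit
to the baseline, 12-month and 36-month observations, with the slope
magnitude clamped to [0, 1]:

```{r}
progression_model(params)
```

Two modeling assumptions matter here and are deliberate:

* **Constant rate.** Decline is linear in expectation over the lifetime,
  an extrapolation from 3 years of follow-up. The one-way and
  probabilistic analyses vary the trajectory inputs to express this
  uncertainty, but non-linear or mixed-effects trajectories are out of
  scope.
* **Single-step dynamics.** At most one TFC state is traversed per year.
  With fitted rates near 0.65/yr this is representable; a rate above
  1/yr would saturate at `p = 1` and under-state decline.

The OLS pipeline reproduces the published transition probabilities
(0.651 for SF1, 0.669 for SF2) to within about 1%; the residual gap
reflects an undocumented regression variant in the original
implementation (weighting or intercept handling), so downstream checks
carry 1.5–3% tolerances rather than exact equality.

### Competing-risk ordering

Background death is applied first each cycle, progression among
survivors: `P(down) = (1 - q)·p`. The ordering is second-order at the
modeled ages (q ranges from ~0.002 at 40 to ~0.27 at 99) but must be
fixed for reproducibility; the alternative ordering changes discounted
life years by well under 1%.

### Discounting and payoffs

Costs and utilities attach to Shoulson–Fahn stages (SF1: TFC 13–11, SF2:
10–7, SF3: 6–3, SF4: 2–1), with one utility shared by SF4–5. Accrual is
at cycle start with factor `(1+d)^(-t)`, `t = 0, 1, …` — the first year
is undiscounted and there is **no half-cycle correction**. This
convention was chosen because it reproduces the published stage-time
identity (discounted SF1-stage person-years = stage QALYs / stage
utility ≈ 2.96 y for the SF1 cohort) to under 1%; a half-cycle-corrected
variant cannot be distinguished on the published evidence and would
shift totals by 1–2%.

**SF5 cost handling.** The parameter table prices SF5 although TFC 0 is
death and accrues no person-time. We default to *not* charging it: in
the published stage 4–5 result cells, stage QALYs divided by the SF4–5
utility already account for the full printed standard-care cost, leaving
no room for an added terminal payment. `sf5_terminal_cost = TRUE`
instead charges the annual SF5 cost once to the mass newly reaching
TFC 0, discounted at its entry cycle, for users who prefer a
death-transition cost.

**Start states.** SF1 cohorts start at TFC 12 and SF2 at TFC 9 (trial
baselines 12.2 and 8.7 rounded to the model grid). TFC 12 is also the
choice validated by the stage-time identity above: starting anywhere
else in SF1 breaks the ≈2.96-year identity.

## Prefunctional-decline cohorts

PFD cohorts (TFC 13, before functional decline) occupy a state with the
population-norm utility (0.86) and zero HD-attributable cost. Onset is
modeled in three steps:

1. **Curve fit.** A logistic CDF in age, `F(a) = plogis((a - μ)/s)`, is
   least-squares fit to cumulative stage-3-onset probabilities per CAG
   stratum (`fit_onset_curve()`). The family is pluggable — any CDF
   function can be passed to `onset_schedule()` — but logistic was
   chosen as the minimal two-parameter monotone sigmoid matching the
   published curves' shape.
2. **Schedule.** Per-year onset weights are CDF increments over the
   modeled window, renormalized by `F(100) - F(40)` so the weights sum
   to one: every survivor experiences onset by the horizon. This
   truncation-renormalization reading follows from the original pooling
   of exactly one subcohort per remaining year to age 100; the
   alternative (discarding post-100 mass into a never-onset residual) is
   representable via the `residual_weight` field.
3. **Pooling.** Subcohort k waits k years in the PFD state under
   background mortality, then enters TFC 13 and progresses at the SF1
   rate; the pooled trace is the weight-averaged mixture
   (`run_pfd_cohort()`).

The packaged onset fixture is **synthetic**: the source staging-system
curves are not published in reusable form, so the fixture reproduces
only their qualitative behaviour (sigmoidal in age; location 58/40/30
years for CAG 40/45/50, i.e. earlier onset at higher CAG, scales 7/6/5
years chosen to span onset over roughly two decades). Consequently PFD
outputs are structurally faithful but not numerically comparable to the
published PFD column, and the test suite checks PFD behaviour by
construction properties (mass conservation, single-subcohort collapse,
explicit mixture oracles, CAG monotonicity) rather than printed values.

The PIN_HD composite (`pin_hd_score()`) is an alternative onset driver:
a configured linear combination of motor score, SDMT and the
CAG-adjusted age product. Its weights and the mapping from score to
annual onset hazard are **configuration**, not packaged constants — the
published composite's coefficients belong to an external survival model
— so `pin_hd_onset_schedule()` takes a pluggable link (default logistic)
and errors without user-supplied coefficients.

## Treatment scenarios

A disease-modifying-treatment scenario is `(delay_years, rate_ratio)`:
progression is arrested during the delay and multiplied by the rate
ratio afterwards (applied directly to the annual probability, since that
probability *is* the fitted yearly rate). The packaged library holds
scenarios A (3 y, 0.75), B (2 y, 0.85), C (1 y, 0.95). For SF1/SF2 the
delay zeroes progression with background mortality still active; for PFD
the default reading **shifts** the whole onset schedule later (mass
pushed past age 100 never onsets), with `pfd_delay_mode = "pause"`
arresting post-onset progression instead. Delays may be fractional: the
boundary year progresses at the remaining fraction of the rate, and
schedule shifts split weights linearly — needed so ±25% one-way analysis
of a 3-year delay is meaningful.

```{r}
evaluate_dmt(hd_parameters("SF2"), "A")
```

## Uncertainty analysis

`run_psa()` re-evaluates the full pipeline over parameter draws:

* 12-month TFC delta ~ normal with sd = (CI width)/3.92; the 36-month
  delta is scaled by the *same* relative draw (perfect correlation —
  the simplest faithful reading of "correlated" parameters, preserving
  the trajectory's shape), and the regression is re-fit per draw so the
  transition probability varies with the regression rather than being
  sampled directly.
* Utilities ~ beta, costs ~ log-normal, both by method of moments from
  the printed mean and 95% interval (sd = width/3.92; the printed mean
  is kept as location even for asymmetric intervals, preserving the
  base case). Zero-dollar lower bounds are floored at 1e-6 for
  log-normal support. Whether the original calibration used method of
  moments is unstated, so credible ranges may differ slightly in the
  tails.
* Optional truncation of delta draws to the reported CI
  (`truncate_ci`), default off.

Credible ranges are empirical 2.5th/97.5th percentiles with linear
interpolation between order statistics (R's type-7 quantile — the
endpoints are sensitive to the rule, so one is fixed and documented).
Draws are deterministic in `(seed, simulation index)`; failed
simulations are surfaced with their indices, never silently dropped.
`run_owsa()` varies one parameter at a time to base × (1 ± 0.25)
(utilities capped at 1, rate ratio capped at 1) and ranks bars by
absolute swing.

## Numerical choices and degenerate inputs

* Mass is conserved to 1e-12 per cycle by construction (tested).
* Median survival interpolates linearly between annual grid points and
  returns `Inf` if survival never crosses 0.5 before the horizon.
* Zero-variance distribution specs collapse to exact point masses (no
  RNG call), so a zero-variance PSA reproduces the base case bit for
  bit.
* Degenerate designs error loudly: identical observation times,
  non-monotone cumulative probabilities, onset curves flat over the
  window, life-table gaps.
* The logistic curve fit optimizes `(μ, log s)` by BFGS from a
  percentile-based initialization; exact logistic inputs are recovered
  to ~1e-6 and the optimum beats a 200×200 grid oracle in tests.

## What the synthetic data establish — and what they do not

The vendored life table is a Gompertz–Makeham curve
(`q(a) = 0.0004 + A·e^{0.0852a}`, `q(60) = 0.00902`) calibrated a priori
to US all-population anchors; it reproduces published natural-history
outputs to 1–2% but is not an official table, and results at ages > 90
lean on the parametric tail. The onset fixture is synthetic (above). A
green test suite therefore establishes that the *pipeline* — regression,
transition structure, pooling, accumulation, uncertainty machinery — is
correct and that SF1/SF2 outputs match the published base case within
stated tolerances; it does not validate the PFD column numerically, nor
either fixture against real vital-statistics or staging-system data.

## Known limitations

Constant-rate, single-step progression; no neuropsychiatric dimension of
burden (TFC does not capture it); cost/utility inputs inherit the small
late-stage samples of their source burden-of-illness study; no DMT
pricing, safety or cost-effectiveness ratios; 40-year-old cohorts by
default (other entry ages are supported but payoffs are age-invariant).
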