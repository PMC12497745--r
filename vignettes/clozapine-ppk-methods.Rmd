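---
title: "Methods: population PK of clozapine and dose individualization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of clozapine and dose individualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clozapk)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the estimation machinery, the synthetic-data
generator, the numerical choices, and what the tests do and do not
demonstrate.

## The model

Clozapine therapy is monitored through trough plasma concentrations drawn
immediately before the next administration. The observable per patient is
therefore a handful of steady-state troughs (occasionally richer), plus the
dosing history, body weight and co-medication. For such data the minimal
structural model consistent with the parameter set (CL/F, V/F, Ka) is a
**one-compartment model with first-order absorption and elimination**; the
bioavailability F is not separately identifiable from oral data and is
absorbed into the apparent parameters (F ≡ 1). We deliberately do not model
two-compartment disposition, absorption transit chains, metabolite
(norclozapine) kinetics or nonlinear elimination; trough-dominated data
cannot identify them.

The statistical model is the standard nonlinear mixed-effects construction:

* **Fixed effects with allometric scaling.** Typical clearance and volume
  scale with body weight relative to a 70 kg reference with the conventional
  exponents 0.75 (clearance) and 1 (volume). Allometry is part of the base
  model, not a searched covariate: weight is known a priori to drive PK, and
  fixing the exponents stabilizes estimation in cohorts spanning 38–120 kg.
* **Covariate effects.** Binary covariates act as linear-fractional factors
  `1 + q·x` (the zopiclone DDI is `1 − 0.254·ZOP` on clearance in the
  reference model); continuous covariates as power forms `(x/median)^q`.
  Factors compose multiplicatively after allometry, so their order is
  irrelevant; any non-positive factor is an invalid-model error, never
  silently clamped.
* **Inter-individual variability.** A single log-normal random effect on
  clearance, `CL_i = CL_tv · exp(η_i)`, `η_i ~ N(0, ω²)`. IIV on volume or
  Ka is omitted: trough sampling carries almost no information about them,
  so trough-dominated cohorts cannot estimate them.
* **Residual error.** Proportional: `Y = X·(1 + ε)`, `ε ~ N(0, σ²)`. The
  error SD scales with the prediction, which matches immunoassay behaviour
  over the clozapine range and makes the error vanish at zero concentration.
* **Ka fixed at 1.3 h⁻¹.** Absorption is essentially unobserved in trough
  data; fixing Ka at a literature value is the standard remedy and is the
  package default (`ka_fixed = TRUE`, overridable).

Units are fixed: hours, mg, kg; concentrations are ng/mL at every interface
(internally mg/L; the conversion factor is exactly 1000).

Steady-state predictions use the closed-form accumulation factors
`1/(1 − e^{−kτ})` per exponential. The `ka → ke` degeneracy is handled by
the analytic limit `D·ka·t·e^{−ka·t}/V` whenever `|ka − ke| < 1e−8·ka`, so
no division by near-zero ever occurs.

## The synthetic cohort generator

The generator (`design_spec()` + `simulate_cohort()`) emulates the kind of
therapeutic-drug-monitoring cohort this analysis targets:

* **n = 81 subjects** by default;
* **weight** log-normal, moment-matched to mean 70.49 / SD 13.53 kg and
  rejection-truncated to [38, 120] kg — log-normal for positivity and the
  mild right skew real weight distributions show;
* **zopiclone prevalence 8/81**;
* **trough-dominated sampling**: two steady-state troughs per subject by
  default. Routine monitoring yields only troughs; how many per
  patient varies by clinic, so 1–3 troughs is an assumption, configurable
  via `n_trough_obs`;
* **dosing** at 8 mg/kg/day split q12h by default (product-label-style
  dosing). The q12h equal split is the
  standard clozapine regimen; q24h/q8h are available via `interval`;
* **steady state**: patients on chronic therapy are simulated at steady
  state. The regimen is encoded as a repeating dose row (closed-form
  steady-state prediction); `n_days` switches to explicit multi-dose
  superposition (14 days q12h reaches the asymptotic trough to well under
  0.1%), and the two representations are cross-checked in the tests.

Because troughs alone identify clearance but barely constrain V/F and Ka,
estimation-oriented studies use an **enriched design**
(`post_dose_sample_times = c(1, 2, 4, 8, 12)`) adding absorption-phase
samples in the final interval. This mirrors how a designed PK study would
sample, and is the configuration used by the parameter-recovery experiments
(200 subjects, 25% zopiclone — a deliberately higher prevalence than 8/81 so
the DDI coefficient is well-conditioned in a cohort of practical size).

Simulated observations can go negative under the proportional-normal
residual at high σ; they are truncated to 0 and the count is reported in the
dataset metadata. The generator records every generative draw
(`true_values()`), enabling exact recovery tests.

What passing tests on these cohorts do **not** show: robustness to assay
censoring (LLOQ), non-adherence, dropout, time-varying covariates, or model
misspecification (the data are generated by the very model being fitted).
Those failure modes require real data.

## Estimation

The marginal likelihood integrates the subject-level random effect out of a
nonlinear model; no closed form exists. `pk_objective()` implements the
**Laplace approximation with interaction**: per subject, an inner search
finds the mode of the conditional joint density of the data and η, the
residual variance is evaluated at the conditional prediction (the
"interaction" part — important for proportional error), and the subject's
−2 log-likelihood contribution is the mode value plus the log-curvature
correction. All 2π constants are kept, so values are directly comparable
with quadrature.

Implementation choices:

* **Inner problem.** One-dimensional and smooth, solved by a damped Newton
  iteration with an analytic η-gradient, vectorized across all subjects
  simultaneously (the curvature comes from central differences of the
  gradient, step h = 1e−4). Convergence: |gradient| < 1e−8 or step size
  below 1e−12; η starts at 0 every evaluation so the objective is a pure
  deterministic function of its arguments (warm starts would make it
  history-dependent).
* **Outer problem.** `stats::nlminb` on transformed parameters: log scale
  for `cl_std`, `v_std`, `omega_cl`, `sigma_prop` (positivity by
  construction), identity for covariate coefficients with an infeasibility
  barrier wherever a factor `1 + q·x ≤ 0`. When the optimizer stalls on the
  flat ridge that a near-zero variance component produces, the fit restarts
  from the incumbent; a stalled point is accepted only if a restart cannot
  improve the objective by more than 0.1.
* **Standard errors.** Numerical Hessian of the objective at the optimum
  (`pracma::hessian`), covariance `2·H⁻¹`, delta method back to the natural
  scale (for a log-parameter the relative SE is the log-scale SE). A
  non-positive-definite Hessian yields `NA` SEs with the weakest direction
  named — never fabricated values.
* **Accuracy.** The test suite holds the Laplace objective within 1% of a
  32-node adaptive Gauss–Hermite quadrature oracle across ω ∈ {0.1, 0.35,
  0.7}, and verifies the ω → 0 limit against the extended-least-squares
  closed form.

**Covariate selection** (`covariate_search()`) is the classical two-step
procedure: forward inclusion of the best candidate while the OFV drop
exceeds 3.84 (χ², 1 df, α = 0.05), then backward elimination unless removal
raises the OFV by more than 6.63 (α = 0.01). The thresholds are the conventional choices for
the two-step procedure. Non-convergent candidate fits are skipped and logged in the
trace, not allowed to crash the search.

## Model qualification

* **CWRES** uses the first-order conditional linearization around the
  empirical-Bayes η: marginal mean `f(η̂) − G·η̂`, covariance
  `G·ω²·Gᵀ + diag(σ²·f_c²)` with `f_c` the conditional predictions,
  decorrelated by Cholesky. This is the de facto standard definition. On
  self-simulated data CWRES is calibrated (mean 0, SD 1 within 3 SE).
* **VPC** simulates replicate datasets under the fitted model with the
  original design, bins observations into quantile-based time bins (6 by
  default; the binning is a presentation choice, not part of the model) and
  compares observed 5th/50th/95th percentiles with their simulated 95%
  envelopes. Bins with fewer than 5 observations are flagged, never
  silently dropped.
* **Bootstrap** resamples subjects with replacement, refits, and reports
  medians, percentile CIs (type-7 interpolation, stated for
  bit-reproducibility), relative SEs, and the bias
  `(median − estimate)/estimate × 100%`. Non-converged replicates are
  excluded and counted; above 10% the report escalates to a warning. The
  replicate count defaults to 1000 (the customary figure).

## Dose individualization

`simulate_scenario()` draws η for `n_sim` virtual patients at a fixed
weight/zopiclone status, computes closed-form steady-state troughs for the
mg/kg/day dose split q12h, and summarizes the probability of landing in the
350–800 ng/mL window (PTA) and of exceeding 1000 ng/mL. Simulated troughs
are *true* concentrations (IIV only) by default: the recommendation concerns
the patient's underlying exposure, not a single noisy measurement; residual
error can be switched on (`residual = TRUE`) where assay-level troughs are
wanted. The simulated dosing interval and the residual-error choice are
design decisions of this package — the published summary does not state
either — and the resulting safety bounds are robust to both (verified in
the acceptance checks).

`pta_grid()` runs the published scenario grid (weights 40–120 kg, doses
1–10 mg/kg/day, 1000 draws per scenario) with deterministic per-scenario
sub-seeds. `recommend_doses()` turns grids into weight-banded tables: per
weight the PTA-maximizing dose (ties to the lower dose, optional toxicity
cap), contiguous weights sharing a dose merged into bands, and the band's
worst-case toxicity exceedance reported as a percent to one decimal. Band
edges can be imposed (reproduction mode, e.g. 50/67/88 kg and 70 kg) or
discovered from dose-switch midpoints on the simulated weight grid; discovery mode is the package's own construction for deriving edges
from a simulated weight grid.

## Numerical details and degenerate inputs

* Dose 0 yields trough 0, PTA 0, toxicity 0 exactly.
* Predictions are floored at 0; the proportional-error variance floors the
  prediction at 1e−8 ng/mL to avoid zero-variance observations in
  pathological designs (observations before any dose).
* Overflowing elimination rates (from extreme η excursions during
  optimization) are capped so `exp(−ke·0)` never produces `Inf·0`; η itself
  is clamped to ±20 inside the inner search.
* All stochastic functions take explicit integer seeds; identical seeds give
  bit-identical results. Grid simulations derive per-scenario sub-seeds
  deterministically below 2³¹.

## Problem sizes in the test suite

The suite favours a few deep checks over many shallow ones, at sizes chosen
to balance statistical resolution against a laptop-scale run: oracle
comparisons on 3–5 subjects; recovery and covariate-search experiments at
200 subjects; power/type-I studies over 20 seeded replicates each; Monte
Carlo oracle checks at 20 000 draws against exact η-integrals (the
steady-state trough is monotone in η, so tail probabilities reduce to normal
CDFs at numerically-solved thresholds — an exact, quadrature-free oracle).

## Known limitations

* Single random effect: no IIV correlation structure, no IIV on V/F or Ka.
* The estimator is Laplace-class; for very sparse or very skewed conditional
  densities SAEM or importance sampling would be more robust — out of scope
  here.
* The recommendation engine optimizes trough-window attainment only; it
  knows nothing of titration schedules, adverse events below 1000 ng/mL, or
  norclozapine ratios.
* All validation is simulation-based self-consistency; agreement with the
  published per-patient diagnostics cannot be checked because the underlying
  clinical dataset is not public.
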