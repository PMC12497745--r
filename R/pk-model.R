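#' Typical (covariate-adjusted) PK parameters
#'
#' Applies allometric weight scaling and covariate effects to the reference
#' population values:
#' `CL = cl_std * (weight/70)^0.75 * (1 + theta_zop * zop) * prod(factors)`,
#' `V = v_std * (weight/70)^1 * prod(factors)`. For the published final model
#' this is `CL/F = 29.6 * (wt/70)^0.75 * (1 - 0.254 * ZOP)`,
#' `V/F = 308 * (wt/70)`.
#'
#' All arguments after `pop` are vectorized over subjects.
#'
#' @param pop A [pop_params()] object.
#' @param weight Body weight(s), kg. Must be positive.
#' @param zop Zopiclone co-administration flag(s), 0/1.
#' @param effects Optional list of extra [covariate_effect()]s applied
#'   multiplicatively after allometry.
#' @param extras Named list/data frame of extra covariate values referenced by
#'   `effects`.
#'
#' @return A tibble with columns `cl` (L/h), `v` (L), `ka` (1/h), one row per
#'   subject.
#' @examples
#' typical_params(pop_params(), weight = c(40, 70, 120), zop = c(1, 0, 0))
#' @export
typical_params <- function(pop, weight, zop = 0, effects = list(),
                           extras = list()) {
  stopifnot(inherits(pop, "clz_pop"))
  if (any(weight <= 0)) stop("`weight` must be positive", call. = FALSE)
  if (!all(zop %in% c(0, 1))) stop("`zop` must be 0 or 1", call. = FALSE)
  n <- max(length(weight), length(zop))
  weight <- rep_len(weight, n)
  zop <- rep_len(zop, n)

  wt_ratio <- weight / pop$ref_weight
  cl <- pop$cl_std * wt_ratio^pop$allo_exp_cl
  v <- pop$v_std * wt_ratio^pop$allo_exp_v

  zop_fac <- 1 + pop$theta_zop * zop
  if (any(zop_fac <= 0)) {
    stop("covariate effect 'zop' on cl yields a non-positive factor",
         call. = FALSE)
  }
  cl <- cl * zop_fac

  for (eff in effects) {
    value <- extras[[eff$name]]
    if (is.null(value)) {
      stop(sprintf("covariate '%s' not found in `extras`", eff$name),
           call. = FALSE)
    }
    fac <- effect_factor(eff, rep_len(value, n))
    if (eff$target == "cl") cl <- cl * fac else v <- v * fac
  }

  tibble::tibble(cl = cl, v = v, ka = rep_len(pop$ka, n))
}

#' Individual PK parameters from a subject-level random effect
#'
#' Realizes `CL_i = CL_tv * exp(eta_cl)`; in the final model the IIV acts on
#' clearance only, so `v` and `ka` pass through unchanged.
#'
#' @param tv Tibble of typical parameters from [typical_params()].
#' @param eta_cl Subject random effect(s) on log clearance.
#' @return A tibble with `cl_i`, `v_i`, `ka_i`, `eta_cl`.
#' @examples
#' tv <- typical_params(pop_params(), weight = 70)
#' individual_params(tv, eta_cl = c(-0.348, 0, 0.348))
#' @export
individual_params <- function(tv, eta_cl = 0) {
  n <- max(nrow(tv), length(eta_cl))
  tibble::tibble(
    cl_i = rep_len(tv$cl, n) * exp(rep_len(eta_cl, n)),
    v_i = rep_len(tv$v, n),
    ka_i = rep_len(tv$ka, n),
    eta_cl = rep_len(eta_cl, n)
  )
}

# One-compartment first-order absorption profile for a single oral dose,
# in mg/L, at time dt (h) after the dose. Handles the ka -> ke degeneracy
# with the analytic limit D*ka*t*exp(-ka*t)/V when |ka - ke| < 1e-8 * ka.
one_cmt_single <- function(amt, v, ke, ka, dt) {
  out <- numeric(length(dt))
  pos <- dt > 0 & amt > 0
  if (!any(pos)) return(out)
  degen <- abs(ka - ke) < 1e-8 * ka
  reg <- pos & !degen
  out[reg] <- amt[reg] * ka[reg] / (v[reg] * (ka[reg] - ke[reg])) *
    (exp(-ke[reg] * dt[reg]) - exp(-ka[reg] * dt[reg]))
  lim <- pos & degen
  out[lim] <- amt[lim] * ka[lim] * dt[lim] * exp(-ka[lim] * dt[lim]) / v[lim]
  pmax(out, 0)
}

# Steady-state profile for a repeating dose every tau h, at phase p in [0, tau).
one_cmt_ss <- function(amt, v, ke, ka, p, tau) {
  degen <- abs(ka - ke) < 1e-8 * ka
  out <- numeric(length(p))
  ok <- amt > 0
  r <- ok & !degen
  out[r] <- amt[r] * ka[r] / (v[r] * (ka[r] - ke[r])) *
    (exp(-ke[r] * p[r]) / (1 - exp(-ke[r] * tau[r])) -
       exp(-ka[r] * p[r]) / (1 - exp(-ka[r] * tau[r])))
  l <- ok & degen
  if (any(l)) {
    # limit of the difference quotient as ke -> ka
    E <- exp(-ka[l] * tau[l])
    out[l] <- amt[l] * ka[l] / v[l] * exp(-ka[l] * p[l]) / (1 - E) *
      (p[l] - tau[l] * E / (1 - E))
  }
  pmax(out, 0)
}

#' Predicted concentration under a dosing history
#'
#' Superposes one-compartment oral single-dose profiles over the dose events.
#' A dose row with a finite `interval` is a repeating steady-state regimen:
#' its contribution is the closed-form steady-state profile evaluated at the
#' phase within the interval. Concentrations are returned in ng/mL (the model
#' works internally in mg/L; the conversion factor is exactly 1000).
#'
#' @param ind One-row tibble (or list) of individual parameters with `cl_i`
#'   (L/h), `v_i` (L), `ka_i` (1/h), e.g. from [individual_params()].
#' @param doses Data frame of dose events: `time` (h), `amount` (mg), optional
#'   `interval` (h, `NA` for a single dose).
#' @param t Time(s) since first dose, h.
#' @return Concentration(s), ng/mL.
#' @examples
#' ind <- individual_params(typical_params(pop_params(), 70), eta_cl = 0)
#' predict_conc(ind, data.frame(time = 0, amount = 560), t = 12)
#' @export
predict_conc <- function(ind, doses, t) {
  stopifnot(nrow(as.data.frame(doses)) >= 1L, all(t >= 0))
  doses <- as.data.frame(doses)
  if (is.null(doses$interval)) doses$interval <- NA_real_
  if (any(doses$amount < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  ke <- ind$cl_i[1] / ind$v_i[1]
  ka <- ind$ka_i[1]
  v <- ind$v_i[1]
  conc <- numeric(length(t))
  for (d in seq_len(nrow(doses))) {
    dt <- t - doses$time[d]
    act <- dt >= 0
    if (!any(act)) next
    nact <- sum(act)
    if (is.finite(doses$interval[d])) {
      tau <- doses$interval[d]
      conc[act] <- conc[act] + one_cmt_ss(
        rep(doses$amount[d], nact), rep(v, nact), rep(ke, nact),
        rep(ka, nact), dt[act] %% tau, rep(tau, nact)
      )
    } else {
      conc[act] <- conc[act] + one_cmt_single(
        rep(doses$amount[d], nact), rep(v, nact), rep(ke, nact),
        rep(ka, nact), dt[act]
      )
    }
  }
  conc * 1000
}

#' Steady-state trough concentration under repeated dosing
#'
#' Closed-form trough (concentration just before the next dose) for a `dose_mg`
#' every `interval_h` regimen, using the accumulation factor
#' `1 / (1 - exp(-k * tau))` for each exponential. Equals the limit of
#' multi-dose superposition.
#'
#' @param ind Individual parameters (tibble/list with `cl_i`, `v_i`, `ka_i`);
#'   columns are vectorized over subjects.
#' @param dose_mg Dose per administration, mg (>= 0).
#' @param interval_h Dosing interval, h (> 0).
#' @return Trough concentration(s), ng/mL.
#' @examples
#' ind <- individual_params(typical_params(pop_params(), 70), eta_cl = 0)
#' steady_state_trough(ind, dose_mg = 280, interval_h = 12)
#' @export
steady_state_trough <- function(ind, dose_mg, interval_h) {
  if (any(dose_mg < 0)) stop("`dose_mg` must be >= 0", call. = FALSE)
  if (any(interval_h <= 0)) stop("`interval_h` must be positive", call. = FALSE)
  n <- max(nrow(as.data.frame(ind)), length(dose_mg), length(interval_h))
  cl <- rep_len(ind$cl_i, n)
  v <- rep_len(ind$v_i, n)
  ka <- rep_len(ind$ka_i, n)
  tau <- rep_len(interval_h, n)
  one_cmt_ss(rep_len(dose_mg, n), v, cl / v, ka, tau, tau) * 1000
}

#' Apply the proportional residual-error model
#'
#' Observation model `Y = X * (1 + eps)`: the residual SD scales with the
#' prediction, so the error vanishes at zero concentration.
#'
#' @param true_conc True (model-predicted) concentration(s), ng/mL, >= 0.
#' @param eps Residual draw(s), typically `rnorm(n, 0, sigma_prop)`.
#' @return Observed concentration(s), ng/mL (may be negative for extreme
#'   negative `eps`; the cohort simulator truncates and flags those).
#' @examples
#' apply_residual(400, eps = 0.257)
#' @export
apply_residual <- function(true_conc, eps) {
  if (any(true_conc < 0)) stop("`true_conc` must be >= 0", call. = FALSE)
  true_conc * (1 + eps)
}
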