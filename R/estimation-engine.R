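# Internal prediction/likelihood engine.
#
# A `clz_engine` is a flattened view of an event-record dataset built once per
# fit: one row per observation plus one row per (observation, contributing
# dose) pair, so concentration predictions and their eta-derivatives for the
# whole cohort are a handful of vectorized operations. Doses with a finite
# `ii` are repeating steady-state regimens handled by the closed-form
# accumulation factors; explicit doses are superposed individually.

build_engine <- function(dataset) {
  obs <- dataset[dataset$evid == 0L, c("id", "time", "dv", "trough")]
  doses <- dataset[dataset$evid == 1L, c("id", "time", "amt", "ii")]
  if (!nrow(obs)) stop("dataset has no observations", call. = FALSE)
  if (!nrow(doses)) stop("dataset has no dose events", call. = FALSE)

  ids <- unique(dataset$id)
  subj_of <- function(id) match(id, ids)
  obs$subj <- subj_of(obs$id)
  doses$subj <- subj_of(doses$id)

  # pair expansion: every dose at or before the observation contributes
  obs_tbl <- tibble::tibble(subj = obs$subj, t_obs = obs$time)
  obs_tbl$obs <- seq_len(nrow(obs_tbl))
  pair <- dplyr::inner_join(
    obs_tbl,
    tibble::tibble(subj = doses$subj, t_dose = doses$time,
                   amt = doses$amt * 1000, # mg -> ng/mL given V in L
                   ii = doses$ii),
    by = "subj", relationship = "many-to-many"
  )
  pair <- pair[pair$t_dose <= pair$t_obs, ]
  dt <- pair$t_obs - pair$t_dose
  pair$is_ss <- is.finite(pair$ii)
  pair$dt <- ifelse(pair$is_ss, dt %% pair$ii, dt)
  pair$tau <- ifelse(pair$is_ss, pair$ii, NA_real_)
  pair <- pair[order(pair$obs), ]
  cov <- dataset_covariates(dataset)
  cov <- cov[match(ids, cov$id), ]

  list(
    ids = ids, n_subj = length(ids),
    obs_subj = obs$subj, y = obs$dv, obs_time = obs$time,
    obs_trough = obs$trough,
    p_obs = pair$obs, p_subj = pair$subj, p_amt = pair$amt,
    p_dt = pair$dt, p_tau = pair$tau, p_ss = pair$is_ss,
    cov = cov
  )
}

# Concentration (ng/mL) and d f / d eta for every observation, given
# per-subject individual clearance cl_i (L/h), volume v (L) and global ka.
engine_pred <- function(eng, cl_i, v, ka) {
  ke_s <- cl_i / v
  ke_s[!is.finite(ke_s)] <- 1e10 # overflow guard: exp(-Inf*0) is NaN
  ke <- ke_s[eng$p_subj]
  vv <- v[eng$p_subj]
  amt <- eng$p_amt
  dt <- eng$p_dt
  dk <- ka - ke
  dk <- ifelse(abs(dk) < 1e-8 * ka, 1e-8 * ka, dk) # degeneracy guard
  B <- amt * ka / (vv * dk)

  f_pair <- numeric(length(dt))
  dfdke <- numeric(length(dt))

  ss <- eng$p_ss
  if (any(ss)) {
    tau <- eng$p_tau[ss]
    Eke <- exp(-ke[ss] * tau)
    D1 <- 1 - Eke
    T1 <- exp(-ke[ss] * dt[ss]) / D1
    T2 <- exp(-ka * dt[ss]) / (1 - exp(-ka * tau))
    f_pair[ss] <- B[ss] * (T1 - T2)
    dT1 <- T1 * (-dt[ss] - tau * Eke / D1)
    dfdke[ss] <- B[ss] / dk[ss] * (T1 - T2) + B[ss] * dT1
  }
  if (any(!ss)) {
    E1 <- exp(-ke[!ss] * dt[!ss])
    E2 <- exp(-ka * dt[!ss])
    f_pair[!ss] <- B[!ss] * (E1 - E2)
    dfdke[!ss] <- B[!ss] / dk[!ss] * (E1 - E2) - B[!ss] * dt[!ss] * E1
  }

  n_obs <- length(eng$y)
  f <- as.vector(rowsum(f_pair, eng$p_obs, reorder = FALSE))
  dfe <- as.vector(rowsum(dfdke * ke, eng$p_obs, reorder = FALSE))
  # rowsum drops absent groups; map back by group labels
  grp <- as.integer(rownames(rowsum(f_pair, eng$p_obs, reorder = FALSE)))
  f_full <- numeric(n_obs)
  d_full <- numeric(n_obs)
  f_full[grp] <- f
  d_full[grp] <- dfe
  list(f = f_full, dfdeta = d_full)
}

# -2 log joint density (per subject) and its eta-gradient at a given eta
# vector, under the proportional-error model with interaction.
inner_eval <- function(eng, eta, cl_tv, v, ka, omega, sigma) {
  cl_i <- cl_tv * exp(eta)
  pr <- engine_pred(eng, cl_i, v, ka)
  f <- pmax(pr$f, 1e-8)
  fp <- pr$dfdeta
  r <- eng$y - f
  s2f2 <- sigma^2 * f^2
  obs_ll <- r^2 / s2f2 + log(2 * pi * s2f2)
  obs_gr <- fp * (-2 * r / s2f2 - 2 * r^2 / (s2f2 * f) + 2 / f)
  g2 <- as.vector(rowsum(obs_ll, eng$obs_subj, reorder = FALSE)) +
    eta^2 / omega^2 + log(2 * pi * omega^2)
  gr <- as.vector(rowsum(obs_gr, eng$obs_subj, reorder = FALSE)) +
    2 * eta / omega^2
  list(g2 = g2, grad = gr, f = f, dfdeta = fp)
}

# Vectorized damped Newton maximization of the per-subject conditional
# (empirical-Bayes) density; returns modes, curvatures and convergence flags.
inner_modes <- function(eng, cl_tv, v, ka, omega, sigma,
                        grad_tol = 1e-8, max_iter = 60L, h = 1e-4) {
  n <- eng$n_subj
  eta <- numeric(n)
  cur <- inner_eval(eng, eta, cl_tv, v, ka, omega, sigma)
  converged <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    up <- inner_eval(eng, eta + h, cl_tv, v, ka, omega, sigma)
    dn <- inner_eval(eng, eta - h, cl_tv, v, ka, omega, sigma)
    g2pp <- (up$grad - dn$grad) / (2 * h)
    g2pp <- pmax(g2pp, 2 / omega^2 * 1e-3, 1e-10)
    step <- -cur$grad / g2pp
    step <- pmin(pmax(step, -2), 2)
    # per-subject backtracking on the joint density
    for (k in 1:12) {
      trial <- inner_eval(eng, eta + step, cl_tv, v, ka, omega, sigma)
      worse <- trial$g2 > cur$g2 + 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    if (any(worse)) {
      trial <- inner_eval(eng, eta + step, cl_tv, v, ka, omega, sigma)
    }
    eta <- pmin(pmax(eta + step, -20), 20)
    cur <- trial
    converged <- abs(cur$grad) < grad_tol | abs(step) < 1e-12
    if (all(converged)) break
  }
  # curvature at the mode for the Laplace determinant term
  up <- inner_eval(eng, eta + h, cl_tv, v, ka, omega, sigma)
  dn <- inner_eval(eng, eta - h, cl_tv, v, ka, omega, sigma)
  g2pp <- (up$grad - dn$grad) / (2 * h)
  list(
    eta = eta, g2 = cur$g2, g2pp = g2pp, grad = cur$grad,
    f = cur$f, dfdeta = cur$dfdeta, converged = converged
  )
}

# Per-subject typical parameters implied by a parameter vector + effects.
engine_typicals <- function(eng, cl_std, v_std, allo_cl, allo_v, ref_wt,
                            effects) {
  w <- eng$cov$weight
  cl_tv <- cl_std * (w / ref_wt)^allo_cl
  v_tv <- v_std * (w / ref_wt)^allo_v
  for (eff in effects) {
    value <- eng$cov[[eff$name]]
    if (is.null(value)) {
      stop(sprintf("covariate '%s' not found in dataset", eff$name),
           call. = FALSE)
    }
    fac <- switch(eff$kind,
      power = (value / eff$s_m)^eff$q,
      linear = 1 + eff$q * value
    )
    if (any(!is.finite(fac)) || any(fac <= 0)) return(NULL) # infeasible
    if (eff$target == "cl") cl_tv <- cl_tv * fac else v_tv <- v_tv * fac
  }
  list(cl_tv = cl_tv, v_tv = v_tv)
}

# Laplace-with-interaction marginal -2 log-likelihood for the whole dataset.
engine_ofv <- function(eng, cl_std, v_std, ka, omega, sigma, allo_cl, allo_v,
                       ref_wt, effects, detail = FALSE) {
  tvs <- engine_typicals(eng, cl_std, v_std, allo_cl, allo_v, ref_wt, effects)
  if (is.null(tvs)) return(if (detail) NULL else 1e10)
  im <- inner_modes(eng, tvs$cl_tv, tvs$v_tv, ka, omega, sigma)
  if (any(im$g2pp <= 0)) return(if (detail) NULL else 1e10)
  contrib <- im$g2 + log(im$g2pp / 2) - log(2 * pi)
  ofv <- sum(contrib)
  if (!is.finite(ofv)) return(if (detail) NULL else 1e10)
  if (!detail) return(ofv)
  list(ofv = ofv, eta = im$eta, g2pp = im$g2pp, f = im$f,
       dfdeta = im$dfdeta, tvs = tvs, inner_converged = im$converged)
}
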