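# Shared fixtures and independent oracles for the suite.

# Published final-model parameter set (70 kg reference).
final_pop <- function(...) pop_params(...)

# Direct closed-form steady-state trough (ng/mL), written independently of
# the package's prediction code.
oracle_ss_trough <- function(cl, v, ka, dose_mg, tau) {
  ke <- cl / v
  1000 * dose_mg * ka / (v * (ka - ke)) *
    (exp(-ke * tau) / (1 - exp(-ke * tau)) -
       exp(-ka * tau) / (1 - exp(-ka * tau)))
}

# Brute-force multi-dose superposition trough: n_doses doses every tau h,
# concentration tau h after the last dose.
oracle_superposition_trough <- function(cl, v, ka, dose_mg, tau, n_doses) {
  ke <- cl / v
  t_obs <- n_doses * tau
  total <- 0
  for (k in seq_len(n_doses)) {
    dt <- t_obs - (k - 1) * tau
    total <- total + dose_mg * ka / (v * (ka - ke)) *
      (exp(-ke * dt) - exp(-ka * dt))
  }
  1000 * total
}

# Adaptive Gauss-Hermite quadrature marginal -2 log-likelihood: the
# independent oracle for the Laplace objective. Centers and scales the
# nodes at each subject's conditional mode.
oracle_gh_ofv <- function(dataset, pop, theta_zop, n_nodes = 32) {
  gh <- pracma::gaussHermite(n_nodes)
  total <- 0
  for (i in unique(dataset$id)) {
    sub <- dataset[dataset$id == i, ]
    obs <- sub[sub$evid == 0, ]
    dref <- sub[sub$evid == 1, ]
    doses <- data.frame(time = dref$time, amount = dref$amt,
                        interval = dref$ii)
    w <- sub$wt[1]
    z <- sub$zop[1]
    cl_tv <- pop$cl_std * (w / 70)^0.75 * (1 + theta_zop * z)
    v_tv <- pop$v_std * (w / 70)
    loglik <- function(eta) {
      ind <- tibble::tibble(cl_i = cl_tv * exp(eta), v_i = v_tv,
                            ka_i = pop$ka)
      f <- predict_conc(ind, doses, obs$time)
      sum(stats::dnorm(obs$dv, f, pop$sigma_prop * f, log = TRUE)) +
        stats::dnorm(eta, 0, pop$omega_cl, log = TRUE)
    }
    m <- stats::optimize(function(e) -loglik(e), c(-5, 5))$minimum
    h <- 1e-4
    curv <- (-loglik(m + h) + 2 * loglik(m) - loglik(m - h)) / h^2
    s <- 1 / sqrt(max(curv, 1e-12))
    vals <- vapply(gh$x, function(x) loglik(m + sqrt(2) * s * x) + x^2, 0)
    M <- max(vals)
    total <- total - 2 * (log(sum(gh$w * exp(vals - M))) + M +
                            log(sqrt(2) * s))
  }
  total
}

# Extended-least-squares -2 log-likelihood: the omega -> 0 limit of the
# marginal objective (proportional error).
oracle_els_ofv <- function(dataset, pop, theta_zop) {
  total <- 0
  for (i in unique(dataset$id)) {
    sub <- dataset[dataset$id == i, ]
    obs <- sub[sub$evid == 0, ]
    dref <- sub[sub$evid == 1, ]
    doses <- data.frame(time = dref$time, amount = dref$amt,
                        interval = dref$ii)
    w <- sub$wt[1]
    z <- sub$zop[1]
    ind <- tibble::tibble(
      cl_i = pop$cl_std * (w / 70)^0.75 * (1 + theta_zop * z),
      v_i = pop$v_std * (w / 70), ka_i = pop$ka
    )
    f <- predict_conc(ind, doses, obs$time)
    total <- total +
      sum((obs$dv - f)^2 / (pop$sigma_prop^2 * f^2) +
            log(pop$sigma_prop^2 * f^2)) +
      nrow(obs) * log(2 * pi)
  }
  total
}

# Exact target-attainment / toxicity probabilities for one scenario: the
# steady-state trough is strictly decreasing in eta, so each exceedance
# probability is a normal CDF at the root of trough(eta) = threshold.
oracle_exact_probs <- function(pop, weight, dose_per_kg, zop,
                               interval_h = 12, target = c(350, 800),
                               toxic = 1000) {
  cl_tv <- pop$cl_std * (weight / 70)^0.75 * (1 + pop$theta_zop * zop)
  v <- pop$v_std * (weight / 70)
  dose_mg <- dose_per_kg * weight / (24 / interval_h)
  tr <- function(eta) {
    oracle_ss_trough(cl_tv * exp(eta), v, pop$ka, dose_mg, interval_h)
  }
  eta_at <- function(thr) {
    stats::uniroot(function(e) tr(e) - thr, c(-12, 12), tol = 1e-12)$root
  }
  p_above <- function(thr) stats::pnorm(eta_at(thr) / pop$omega_cl)
  list(
    p_toxic = p_above(toxic),
    pta = p_above(target[1]) - p_above(target[2]),
    p_below = 1 - p_above(target[1])
  )
}

# Small enriched-design simulated cohort used by several estimation tests.
make_enriched <- function(n = 40, seed = 7, pop = final_pop(), p_zop = 0.25,
                          times = c(2, 8)) {
  simulate_cohort(pop, design_spec(
    n_subjects = n, p_zop = p_zop, seed = seed,
    n_trough_obs = 1, post_dose_sample_times = times
  ))
}
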