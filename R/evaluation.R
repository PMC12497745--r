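# Simulate replicate observation vectors under a fitted/assumed model with
# the original design (same subjects, doses, times). Returns an
# n_obs x n_sim matrix of observed (residual-perturbed) concentrations.
simulate_replicates <- function(eng, pop, effects, n_sim, seed,
                                residual = TRUE) {
  set.seed(seed)
  tvs <- engine_typicals(eng, pop$cl_std, pop$v_std, pop$allo_exp_cl,
                         pop$allo_exp_v, pop$ref_weight, effects)
  n_obs <- length(eng$y)
  out <- matrix(0, n_obs, n_sim)
  for (s in seq_len(n_sim)) {
    eta <- stats::rnorm(eng$n_subj, 0, pop$omega_cl)
    f <- engine_pred(eng, tvs$cl_tv * exp(eta), tvs$v_tv, pop$ka)$f
    y <- if (residual) {
      pmax(f * (1 + stats::rnorm(n_obs, 0, pop$sigma_prop)), 0)
    } else {
      f
    }
    out[, s] <- y
  }
  out
}

#' Goodness-of-fit records (PRED, IPRED, CWRES)
#'
#' One row per observation: the population prediction `pred` (all random
#' effects at zero), the individual prediction `ipred` (at the subject's
#' empirical-Bayes eta) and the conditional weighted residual `cwres`. CWRES
#' uses the first-order conditional linearization around the EBE: the
#' subject's marginal mean is `f(eta_hat) - G * eta_hat`, the covariance is
#' `G %*% omega^2 %*% t(G)` plus the diagonal proportional residual variance
#' at the conditional predictions, and residuals are decorrelated by the
#' Cholesky factor.
#'
#' @param fit A converged `clz_fit`.
#' @return Tibble of class `clz_gof`: `id`, `time`, `dv`, `pred`, `ipred`,
#'   `cwres`.
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "clz_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  eng <- build_engine(fit$dataset)
  pop <- fit$pop
  tvs <- engine_typicals(eng, pop$cl_std, pop$v_std, pop$allo_exp_cl,
                         pop$allo_exp_v, pop$ref_weight, fit$effects)
  pred <- engine_pred(eng, tvs$cl_tv, tvs$v_tv, pop$ka)$f

  eta_hat <- fit$ebes$eta_cl
  pc <- engine_pred(eng, tvs$cl_tv * exp(eta_hat), tvs$v_tv, pop$ka)
  ipred <- pc$f
  G <- pc$dfdeta

  cwres <- numeric(length(eng$y))
  for (i in seq_len(eng$n_subj)) {
    idx <- which(eng$obs_subj == i)
    Gi <- G[idx]
    mean_i <- ipred[idx] - Gi * eta_hat[i]
    cov_i <- pop$omega_cl^2 * tcrossprod(Gi) +
      diag(pop$sigma_prop^2 * pmax(ipred[idx], 1e-8)^2,
           nrow = length(idx))
    L <- tryCatch(chol(cov_i), error = function(e) NULL)
    if (is.null(L)) {
      stop(sprintf("singular conditional covariance for subject %s",
                   eng$ids[i]), call. = FALSE)
    }
    cwres[idx] <- backsolve(L, eng$y[idx] - mean_i, transpose = TRUE)
  }
  out <- tibble::tibble(
    id = eng$ids[eng$obs_subj], time = eng$obs_time, dv = eng$y,
    pred = pred, ipred = ipred, cwres = cwres
  )
  class(out) <- c("clz_gof", class(out))
  out
}

#' Visual predictive check summary
#'
#' Simulates `n_sim` replicate datasets under the fitted model with the
#' original design (same covariates, doses and sampling times), bins
#' observations by time (quantile-based bins) and, per bin, compares the
#' observed 5th/50th/95th percentiles with the simulation-based 95%
#' confidence interval of each percentile. Bins holding fewer than 5
#' observations are flagged, not dropped.
#'
#' @param fit A converged `clz_fit`.
#' @param n_sim Number of replicate datasets (>= 1; >= 100 recommended,
#'   default 1000).
#' @param seed Integer seed.
#' @param bins Number of time bins.
#' @param probs Percentiles summarized.
#' @return Tibble of class `clz_vpc`: one row per (bin, percentile) with the
#'   observed value and the simulated lower/median/upper envelope.
#' @export
vpc <- function(fit, n_sim = 1000, seed = 1L, bins = 6,
                probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(fit, "clz_fit"), n_sim >= 1)
  eng <- build_engine(fit$dataset)
  brk <- unique(stats::quantile(eng$obs_time, probs = seq(0, 1, length.out = bins + 1),
                                type = 7))
  if (length(brk) < 2) brk <- c(brk - 0.5, brk + 0.5)
  bin <- droplevels(cut(eng$obs_time, breaks = brk, include.lowest = TRUE))
  bin <- droplevels(bin, exclude = levels(bin)[table(bin) == 0])
  sims <- simulate_replicates(eng, fit$pop, fit$effects, n_sim, seed)

  lv <- levels(bin)
  rows <- list()
  for (b in seq_along(lv)) {
    idx <- which(bin == lv[b])
    obs_q <- stats::quantile(eng$y[idx], probs, type = 7)
    sim_q <- apply(sims[idx, , drop = FALSE], 2, stats::quantile,
                   probs = probs, type = 7)
    if (length(probs) == 1L) sim_q <- matrix(sim_q, nrow = 1)
    ci <- apply(sim_q, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
                type = 7)
    rows[[b]] <- tibble::tibble(
      bin = lv[b],
      time_mid = stats::median(eng$obs_time[idx]),
      n_obs = length(idx),
      flagged = length(idx) < 5,
      percentile = 100 * probs,
      observed = unname(obs_q),
      sim_lo = ci[1, ], sim_med = ci[2, ], sim_hi = ci[3, ]
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  class(out) <- c("clz_vpc", class(out))
  out
}

#' Percent bias of a bootstrap median against the point estimate
#'
#' `(median - estimate) / estimate * 100`, the prediction-error metric used
#' in bootstrap model qualification tables.
#'
#' @param estimate Point estimate(s) from the original fit.
#' @param boot_median Bootstrap median(s).
#' @return Bias in percent.
#' @examples
#' bias_pct(29.6, 29.4) # -0.68
#' @export
bias_pct <- function(estimate, boot_median) {
  (boot_median - estimate) / estimate * 100
}

#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement (same cohort size), refits each
#' replicate starting from the original estimates, and summarizes each
#' parameter by its bootstrap median, percentile 95% CI (2.5th/97.5th,
#' type-7 interpolation), relative SE and percent bias
#' `(median - estimate)/estimate * 100`. Non-converged replicates are
#' excluded and counted; a warning escalates when they exceed 10%.
#'
#' @param fit A converged `clz_fit` (defines data, model and point estimates).
#' @param n_rep Number of bootstrap replicates (default 1000).
#' @param seed Integer seed driving the resampling.
#' @return A `clz_boot` object; `tidy()` gives the summary table.
#' @export
pk_bootstrap <- function(fit, n_rep = 1000, seed = 1L) {
  stopifnot(inherits(fit, "clz_fit"), n_rep >= 1)
  dataset <- fit$dataset
  ids <- unique(dataset$id)
  n <- length(ids)
  set.seed(seed)

  draws <- matrix(NA_real_, n_rep, length(fit$par_names),
                  dimnames = list(NULL, fit$par_names))
  n_fail <- 0L
  by_id <- split(as.data.frame(dataset), dataset$id)
  for (r in seq_len(n_rep)) {
    take <- sample(ids, n, replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      piece <- by_id[[as.character(take[k])]]
      piece$id <- k
      piece
    })
    rep_ds <- as_pk_dataset(dplyr::bind_rows(pieces))
    f <- tryCatch(
      pk_fit(rep_ds, init = fit$pop, effects = fit$effects,
             estimate_ka = fit$estimate_ka, se = FALSE),
      error = function(e) NULL
    )
    if (is.null(f) || !f$converged) {
      n_fail <- n_fail + 1L
      next
    }
    draws[r, ] <- fit_estimates(f)
  }
  if (n_fail > 0.1 * n_rep) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_fail, n_rep), call. = FALSE)
  }
  ok <- stats::complete.cases(draws)
  est <- fit_estimates(fit)
  kept <- draws[ok, , drop = FALSE]
  med <- unname(apply(kept, 2, stats::median))
  summ <- tibble::tibble(
    term = fit$par_names,
    estimate = unname(est),
    boot_median = med,
    ci_lo = unname(apply(kept, 2, stats::quantile, probs = 0.025, type = 7)),
    ci_hi = unname(apply(kept, 2, stats::quantile, probs = 0.975, type = 7)),
    boot_se_pct = 100 * unname(apply(kept, 2, stats::sd)) / abs(unname(est)),
    bias_pct = bias_pct(unname(est), med)
  )
  structure(
    list(summary = summ, draws = draws[ok, , drop = FALSE],
         n_rep = n_rep, n_failed = n_fail, seed = seed),
    class = "clz_boot"
  )
}

#' @export
print.clz_boot <- function(x, ...) {
  cat(sprintf("<clz_boot> %d replicates (%d non-converged, excluded)\n",
              x$n_rep, x$n_failed))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname pk_bootstrap
#' @param x A `clz_boot`.
#' @param ... Unused.
#' @export
tidy.clz_boot <- function(x, ...) x$summary

#' Individual prediction profiles
#'
#' Dense concentration-time curves per subject: the population prediction
#' (`pred`, eta = 0) and the individual prediction (`ipred`, at the EBE),
#' with the subject's observations attached for plotting. The grid runs from
#' zero to the last observation time plus one dosing interval.
#'
#' @param fit A converged `clz_fit`.
#' @param n_grid Grid points per subject.
#' @return Tibble of class `clz_profiles` with `id`, `time`, `pred`, `ipred`
#'   and an `obs` list-column mirror via `dv` rows (`dv` is `NA` on grid
#'   rows).
#' @export
individual_profiles <- function(fit, n_grid = 101) {
  stopifnot(inherits(fit, "clz_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  dataset <- fit$dataset
  eng <- build_engine(dataset)
  pop <- fit$pop
  tvs <- engine_typicals(eng, pop$cl_std, pop$v_std, pop$allo_exp_cl,
                         pop$allo_exp_v, pop$ref_weight, fit$effects)
  rows <- list()
  for (i in seq_len(eng$n_subj)) {
    id_i <- eng$ids[i]
    d <- dataset[dataset$id == id_i & dataset$evid == 1L, ]
    doses <- tibble::tibble(time = d$time, amount = d$amt, interval = d$ii)
    obs_t <- eng$obs_time[eng$obs_subj == i]
    tau <- if (any(is.finite(d$ii))) max(d$ii, na.rm = TRUE) else
      max(diff(sort(unique(d$time))), 12)
    t_end <- max(obs_t) + tau
    grid <- seq(0, t_end, length.out = n_grid)
    ind_pop <- tibble::tibble(cl_i = tvs$cl_tv[i], v_i = tvs$v_tv[i],
                              ka_i = pop$ka)
    ind_ebe <- tibble::tibble(
      cl_i = tvs$cl_tv[i] * exp(fit$ebes$eta_cl[i]),
      v_i = tvs$v_tv[i], ka_i = pop$ka
    )
    rows[[i]] <- dplyr::bind_rows(
      tibble::tibble(
        id = id_i, time = grid, type = "curve",
        pred = predict_conc(ind_pop, doses, grid),
        ipred = predict_conc(ind_ebe, doses, grid),
        dv = NA_real_
      ),
      tibble::tibble(
        id = id_i, time = obs_t, type = "obs",
        pred = NA_real_, ipred = NA_real_,
        dv = eng$y[eng$obs_subj == i]
      )
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("clz_profiles", class(out))
  out
}
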