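#' Marginal -2 log-likelihood (OFV) of the mixed-effects model
#'
#' Evaluates the Laplace-with-interaction approximation to the marginal
#' -2 log-likelihood: per subject an inner Newton search finds the mode of the
#' conditional density of `eta_cl`, the proportional residual variance is
#' evaluated at the conditional prediction, and the subject contribution is
#' the mode value plus the log-curvature correction. Deterministic given its
#' inputs; includes all `2*pi` normalizing constants so values are directly
#' comparable with quadrature.
#'
#' @param dataset A `clz_dataset`.
#' @param pop A [pop_params()] holding `cl_std`, `v_std`, `ka`, `omega_cl`,
#'   `sigma_prop` (the `theta_zop` slot is ignored here; model covariates are
#'   given explicitly).
#' @param effects List of [covariate_effect()]s defining the covariate model.
#' @return The OFV (scalar). If any subject's inner search fails to converge,
#'   the value carries attribute `inner_converged = FALSE`.
#' @examples
#' ds <- simulate_cohort(pop_params(), design_spec(n_subjects = 5, seed = 1))
#' pk_objective(ds, pop_params(), effects = zop_effect(-0.254))
#' @export
pk_objective <- function(dataset, pop, effects = list()) {
  stopifnot(inherits(pop, "clz_pop"))
  eng <- build_engine(as_pk_dataset(dataset))
  det <- engine_ofv(eng, pop$cl_std, pop$v_std, pop$ka,
                    max(pop$omega_cl, 1e-10), pop$sigma_prop,
                    pop$allo_exp_cl, pop$allo_exp_v, pop$ref_weight,
                    effects, detail = TRUE)
  if (is.null(det)) stop("objective undefined at these parameters", call. = FALSE)
  out <- det$ofv
  if (!all(det$inner_converged)) attr(out, "inner_converged") <- FALSE
  out
}

#' The zopiclone-on-clearance covariate effect
#'
#' Convenience constructor for the drug-drug interaction term of the final
#' model: a linear-fractional factor `1 + q * ZOP` on clearance
#' (`q = -0.254` published).
#'
#' @param q Coefficient (fraction change in clearance when `zop = 1`).
#' @return A list containing one [covariate_effect()].
#' @export
zop_effect <- function(q = -0.254) {
  list(covariate_effect("cl", "zop", kind = "linear", q = q))
}

#' Fit the population PK model by Laplace approximation
#'
#' Minimizes [pk_objective()] over log-transformed positive parameters
#' (`cl_std`, `v_std`, `omega_cl`, `sigma_prop`, optionally `ka`) and
#' untransformed covariate coefficients, using [stats::nlminb()]. `ka` is
#' fixed at its initial value by default, as in the published analysis.
#' Standard errors come from the numerical Hessian of the objective at the
#' optimum (covariance `2 * H^-1`), reported as percent relative SEs on the
#' natural scale via the delta method; they are `NA` (with a message
#' attribute) when the Hessian is not positive definite, never fabricated.
#'
#' @param dataset A `clz_dataset`.
#' @param init A [pop_params()] of initial values (defaults: published model).
#' @param effects Covariate model, list of [covariate_effect()]s; their `q`
#'   values are estimated starting from the values supplied.
#' @param estimate_ka Estimate `ka` instead of fixing it.
#' @param se Compute standard errors (skip for speed inside searches).
#' @param control Passed to [stats::nlminb()].
#' @return A `clz_fit` object; see [tidy.clz_fit()], [glance.clz_fit()],
#'   [gof()], [vpc()], [pk_bootstrap()].
#' @examples
#' \donttest{
#' ds <- simulate_cohort(pop_params(), design_spec(n_subjects = 30, seed = 2,
#'   post_dose_sample_times = c(2, 6, 12)))
#' fit <- pk_fit(ds, effects = zop_effect())
#' tidy(fit)
#' }
#' @export
pk_fit <- function(dataset, init = pop_params(), effects = list(),
                   estimate_ka = !init$ka_fixed, se = TRUE,
                   control = list()) {
  dataset <- as_pk_dataset(dataset)
  eng <- build_engine(dataset)
  n_eff <- length(effects)

  par0 <- c(log(init$cl_std), log(init$v_std))
  nm <- c("cl_std", "v_std")
  if (estimate_ka) {
    par0 <- c(par0, log(init$ka)); nm <- c(nm, "ka")
  }
  if (n_eff) {
    par0 <- c(par0, vapply(effects, function(e) e$q, 0))
    nm <- c(nm, vapply(effects, function(e) paste0("q_", e$name), ""))
  }
  par0 <- c(par0, log(max(init$omega_cl, 1e-3)), log(init$sigma_prop))
  nm <- c(nm, "omega_cl", "sigma_prop")
  names(par0) <- nm
  is_log <- !grepl("^q_", nm)

  n_evals <- 0L
  unpack <- function(par) {
    i <- 1L
    cl_std <- exp(par[i]); i <- i + 1L
    v_std <- exp(par[i]); i <- i + 1L
    ka <- if (estimate_ka) { k <- exp(par[i]); i <- i + 1L; k } else init$ka
    effs <- effects
    if (n_eff) for (j in seq_len(n_eff)) {
      effs[[j]]$q <- unname(par[i]); i <- i + 1L
    }
    omega <- exp(par[i]); i <- i + 1L
    sigma <- exp(par[i])
    list(cl_std = cl_std, v_std = v_std, ka = ka, effects = effs,
         omega = omega, sigma = sigma)
  }
  obj <- function(par) {
    n_evals <<- n_evals + 1L
    p <- unpack(par)
    engine_ofv(eng, p$cl_std, p$v_std, p$ka, p$omega, p$sigma,
               init$allo_exp_cl, init$allo_exp_v, init$ref_weight, p$effects)
  }

  lower <- ifelse(is_log, -12, -Inf)
  upper <- ifelse(is_log, 12, Inf)
  ctl <- utils::modifyList(list(eval.max = 3000, iter.max = 600), control)
  opt <- stats::nlminb(par0, obj, lower = lower, upper = upper, control = ctl)
  # restart from the incumbent when the optimizer stalls on a flat ridge
  # (near-degenerate variance components); accept a stalled solution only
  # if a restart cannot improve the objective meaningfully
  outer_ok <- opt$convergence == 0
  if (!outer_ok) {
    for (k in 1:2) {
      opt2 <- stats::nlminb(opt$par, obj, lower = lower, upper = upper,
                            control = ctl)
      improved <- opt$objective - opt2$objective
      if (opt2$objective <= opt$objective) opt <- opt2
      if (opt$convergence == 0) {
        outer_ok <- TRUE
        break
      }
      if (improved < 0.1 &&
          grepl("false convergence|singular convergence", opt$message)) {
        outer_ok <- TRUE # stationary: estimates usable, message retained
        break
      }
    }
  }

  p <- unpack(opt$par)
  det <- engine_ofv(eng, p$cl_std, p$v_std, p$ka, p$omega, p$sigma,
                    init$allo_exp_cl, init$allo_exp_v, init$ref_weight,
                    p$effects, detail = TRUE)
  converged <- outer_ok && !is.null(det) && all(det$inner_converged)

  # fold a fitted zopiclone effect back into the population object so the
  # simulation/dosing side can consume the fit directly
  zop_q <- 0
  for (e in p$effects) {
    if (e$name == "zop" && e$target == "cl" && e$kind == "linear") zop_q <- e$q
  }
  est <- pop_params(
    cl_std = p$cl_std, v_std = p$v_std, ka = p$ka,
    ka_fixed = !estimate_ka, theta_zop = zop_q,
    allo_exp_cl = init$allo_exp_cl, allo_exp_v = init$allo_exp_v,
    omega_cl = p$omega, sigma_prop = p$sigma, ref_weight = init$ref_weight
  )

  fit <- structure(
    list(
      pop = est, effects = p$effects, ofv = opt$objective,
      par = opt$par, par_names = nm, is_log = is_log,
      se_pct = stats::setNames(rep(NA_real_, length(nm)), nm),
      se_message = NULL,
      ebes = tibble::tibble(id = eng$ids, eta_cl = det$eta),
      converged = converged, n_function_evals = n_evals,
      objective_fn = obj, init = init, estimate_ka = estimate_ka,
      dataset = dataset
    ),
    class = "clz_fit"
  )
  if (se) fit <- add_standard_errors(fit)
  fit
}

# Numerical-Hessian standard errors at the optimum; delta method maps
# log-scale SEs to percent relative SEs on the natural scale.
add_standard_errors <- function(fit) {
  H <- pracma::hessian(fit$objective_fn, fit$par)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    dir <- fit$par_names[which.min(diag(H))]
    fit$se_message <- sprintf(
      "Hessian not positive definite (weakest direction: %s); SEs unavailable",
      dir
    )
    return(fit)
  }
  covm <- 2 * solve(H)
  se_t <- sqrt(pmax(diag(covm), 0))
  se_pct <- ifelse(fit$is_log, 100 * se_t, 100 * se_t / abs(fit$par))
  names(se_pct) <- fit$par_names
  fit$se_pct <- se_pct
  fit
}

#' Standard errors of a fitted model
#'
#' Recomputes the relative standard errors (%) from the numerical Hessian of
#' the objective at the optimum. Errors if the fit did not converge or the
#' Hessian is not positive definite.
#'
#' @param fit A converged `clz_fit`.
#' @return Named vector of percent relative SEs.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "clz_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  fit <- add_standard_errors(fit)
  if (!is.null(fit$se_message)) stop(fit$se_message, call. = FALSE)
  fit$se_pct
}

#' @export
print.clz_fit <- function(x, ...) {
  cat("<clz_fit> Laplace fit of the clozapine PPK model\n")
  cat(sprintf("  OFV %.3f | %s | %d subjects | %d objective evaluations\n",
              x$ofv, if (x$converged) "converged" else "NOT converged",
              nrow(x$ebes), x$n_function_evals))
  print(tidy(x), n = Inf)
  if (!is.null(x$se_message)) cat("  note:", x$se_message, "\n")
  invisible(x)
}

# Natural-scale estimates by parameter name (aligned with par_names).
fit_estimates <- function(fit) {
  est <- ifelse(fit$is_log, exp(fit$par), fit$par)
  stats::setNames(unname(est), fit$par_names)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy parameter table of a fitted model
#'
#' @param x A `clz_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `se_pct` (percent relative SE),
#'   plus fixed `ka` when it was not estimated.
#' @export
tidy.clz_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = x$par_names,
    estimate = unname(fit_estimates(x)),
    se_pct = unname(x$se_pct)
  )
  if (!x$estimate_ka) {
    out <- dplyr::bind_rows(
      out[1:2, ],
      tibble::tibble(term = "ka", estimate = x$pop$ka, se_pct = NA_real_),
      out[-(1:2), ]
    )
  }
  out
}

#' One-row summary of a fitted model
#'
#' @param x A `clz_fit`.
#' @param ... Unused.
#' @return Tibble with `ofv`, `n_subjects`, `n_obs`, `converged`,
#'   `n_function_evals`.
#' @export
glance.clz_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv,
    n_subjects = nrow(x$ebes),
    n_obs = sum(x$dataset$evid == 0L),
    converged = x$converged,
    n_function_evals = x$n_function_evals
  )
}
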