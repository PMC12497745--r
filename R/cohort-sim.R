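#' Design of a synthetic clozapine cohort
#'
#' Captures everything the cohort generator needs: cohort size, the weight
#' distribution (log-normal moment-matched to the study's mean 70.49 /
#' SD 13.53 kg, truncated by rejection to 38-120 kg), the zopiclone
#' co-medication prevalence (8 of 81 in the study), the dosing regimen and the
#' sampling schedule. The default schedule is trough-dominated (two
#' steady-state troughs per subject), matching therapeutic drug monitoring
#' practice; `post_dose_sample_times` enriches the final interval with
#' absorption-phase samples for estimation work where V/F would otherwise be
#' weakly identified.
#'
#' @param n_subjects Number of subjects.
#' @param weight_mean,weight_sd Target mean and SD of body weight, kg.
#' @param weight_bounds Length-2 truncation bounds, kg.
#' @param p_zop Fraction of subjects on zopiclone.
#' @param dose_per_kg Total daily clozapine dose, mg/kg/day, split equally
#'   across administrations.
#' @param interval Dosing interval, h.
#' @param n_trough_obs Number of steady-state trough observations per subject.
#' @param post_dose_sample_times Optional vector of sampling times (h after
#'   the final dose) added to the schedule, e.g. `c(1, 2, 4, 8, 12)`.
#' @param n_days If `NULL` (default) the regimen is encoded as a repeating
#'   steady-state dose row (closed-form prediction); otherwise that many days
#'   of explicit dose events are emitted before sampling.
#' @param seed Integer seed making the generated cohort reproducible.
#'
#' @return A `clz_design` list.
#' @examples
#' design_spec(n_subjects = 20, seed = 7)
#' @export
design_spec <- function(n_subjects = 81,
                        weight_mean = 70.49,
                        weight_sd = 13.53,
                        weight_bounds = c(38, 120),
                        p_zop = 8 / 81,
                        dose_per_kg = 8,
                        interval = 12,
                        n_trough_obs = 2,
                        post_dose_sample_times = NULL,
                        n_days = NULL,
                        seed = 1L) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (p_zop < 0 || p_zop > 1) stop("`p_zop` must be in [0, 1]", call. = FALSE)
  if (any(weight_bounds <= 0) || diff(weight_bounds) <= 0) {
    stop("`weight_bounds` must be increasing and positive", call. = FALSE)
  }
  if (interval <= 0 || interval > 24) {
    stop("`interval` must be in (0, 24] h", call. = FALSE)
  }
  if (n_trough_obs < 0) stop("`n_trough_obs` must be >= 0", call. = FALSE)
  if (n_trough_obs == 0 && length(post_dose_sample_times) == 0) {
    stop("design yields zero observations per subject", call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      weight_mean = weight_mean, weight_sd = weight_sd,
      weight_bounds = weight_bounds, p_zop = p_zop,
      dose_per_kg = dose_per_kg, interval = interval,
      n_trough_obs = as.integer(n_trough_obs),
      post_dose_sample_times = post_dose_sample_times,
      n_days = n_days, seed = as.integer(seed)
    ),
    class = "clz_design"
  )
}

# Log-normal parameters matched to an arithmetic mean and SD.
lnorm_match <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  list(meanlog = meanlog, sdlog = sdlog)
}

#' Sample cohort covariates (weight, zopiclone flag)
#'
#' Weights are log-normal (moment-matched to `weight_mean` / `weight_sd`) and
#' rejection-truncated to `weight_bounds`; zopiclone flags are Bernoulli with
#' probability `p_zop`. Reproducible given `design$seed`.
#'
#' @param design A [design_spec()].
#' @return Tibble with `id`, `weight` (kg), `zop` (0/1).
#' @examples
#' sample_cohort(design_spec(n_subjects = 10, seed = 42))
#' @export
sample_cohort <- function(design) {
  stopifnot(inherits(design, "clz_design"))
  lp <- lnorm_match(design$weight_mean, design$weight_sd)
  lo <- design$weight_bounds[1]
  hi <- design$weight_bounds[2]
  mass <- stats::plnorm(hi, lp$meanlog, lp$sdlog) -
    stats::plnorm(lo, lp$meanlog, lp$sdlog)
  if (mass < 1e-3) {
    stop("weight bounds exclude essentially all of the weight distribution",
         call. = FALSE)
  }
  n <- design$n_subjects
  withr_seed <- design$seed
  set.seed(withr_seed)
  weights <- numeric(0)
  while (length(weights) < n) {
    draw <- stats::rlnorm(max(2L * n, 50L), lp$meanlog, lp$sdlog)
    weights <- c(weights, draw[draw >= lo & draw <= hi])
  }
  weights <- weights[seq_len(n)]
  zop <- stats::rbinom(n, 1L, design$p_zop)
  tibble::tibble(id = seq_len(n), weight = weights, zop = zop)
}

# Observation schedule (times in h since first dose, trough flag) for a
# regimen with `n_dose` administrations every `interval` h.
obs_schedule <- function(design, n_dose) {
  tau <- design$interval
  times <- numeric(0)
  trough <- logical(0)
  if (design$n_trough_obs > 0) {
    k <- (n_dose - design$n_trough_obs + 1):n_dose
    times <- c(times, k * tau)
    trough <- c(trough, rep(TRUE, length(k)))
  }
  if (length(design$post_dose_sample_times)) {
    tt <- (n_dose - 1) * tau + design$post_dose_sample_times
    keep <- !(tt %in% times)
    times <- c(times, tt[keep])
    trough <- c(trough, design$post_dose_sample_times[keep] == tau)
  }
  ord <- order(times)
  list(times = times[ord], trough = trough[ord])
}

#' Simulate a trough-sampled clozapine dataset
#'
#' Generates the full event-record dataset from the generative direction of
#' the fitted model: covariates from [sample_cohort()], per-subject
#' `eta_cl ~ N(0, omega_cl^2)`, a q-`interval` regimen at `dose_per_kg`
#' mg/kg/day, true concentrations from the structural model and proportional
#' residual error `Y = X * (1 + eps)` with `eps ~ N(0, sigma_prop^2)`.
#' Negative simulated observations are truncated to 0 and counted in the
#' metadata.
#'
#' @param pop A [pop_params()] object (the generative truth).
#' @param design A [design_spec()].
#' @return An event-record tibble of class `clz_dataset` with columns `id`,
#'   `time` (h), `amt` (mg), `ii` (h, repeating-regimen interval, `NA`
#'   otherwise), `dv` (ng/mL), `evid`, `mdv`, `wt`, `zop`, `trough`.
#'   Attributes: `meta` (seed, design, truncation count) and `truth`
#'   (the per-subject generative draws, see [true_values()]).
#' @examples
#' ds <- simulate_cohort(pop_params(), design_spec(n_subjects = 5, seed = 1))
#' dplyr::count(ds, evid)
#' @export
simulate_cohort <- function(pop, design) {
  stopifnot(inherits(pop, "clz_pop"), inherits(design, "clz_design"))
  cov <- sample_cohort(design)
  n <- nrow(cov)
  # sample_cohort seeds the stream; subsequent draws continue it
  eta <- stats::rnorm(n, 0, pop$omega_cl)

  tau <- design$interval
  n_per_day <- 24 / tau
  explicit <- !is.null(design$n_days)
  n_dose <- if (explicit) as.integer(design$n_days * n_per_day) else 28L
  sched <- obs_schedule(design, n_dose)

  tv <- typical_params(pop, cov$weight, cov$zop)
  ind <- individual_params(tv, eta)

  rows <- vector("list", n)
  n_trunc <- 0L
  for (i in seq_len(n)) {
    amt_i <- design$dose_per_kg * cov$weight[i] / n_per_day
    if (explicit) {
      dose_tbl <- tibble::tibble(
        time = (seq_len(n_dose) - 1) * tau,
        amount = amt_i, interval = NA_real_
      )
    } else {
      dose_tbl <- tibble::tibble(time = 0, amount = amt_i, interval = tau)
    }
    true_c <- predict_conc(ind[i, ], dose_tbl, sched$times)
    eps <- stats::rnorm(length(true_c), 0, pop$sigma_prop)
    y <- apply_residual(true_c, eps)
    neg <- y < 0
    n_trunc <- n_trunc + sum(neg)
    y[neg] <- 0

    dose_rows <- tibble::tibble(
      id = i, time = dose_tbl$time, amt = dose_tbl$amount,
      ii = dose_tbl$interval, dv = NA_real_, evid = 1L, mdv = 1L,
      wt = cov$weight[i], zop = cov$zop[i], trough = NA
    )
    obs_rows <- tibble::tibble(
      id = i, time = sched$times, amt = NA_real_, ii = NA_real_,
      dv = y, evid = 0L, mdv = 0L,
      wt = cov$weight[i], zop = cov$zop[i], trough = sched$trough
    )
    rows[[i]] <- dplyr::bind_rows(dose_rows, obs_rows)
  }
  ds <- dplyr::bind_rows(rows)
  truth <- tibble::tibble(
    id = cov$id, weight = cov$weight, zop = cov$zop, eta_cl = eta,
    cl_tv = tv$cl, v_tv = tv$v,
    cl_i = ind$cl_i, v_i = ind$v_i, ka_i = ind$ka_i
  )
  attr(ds, "meta") <- list(
    seed = design$seed, design = design, generator = "simulate_cohort",
    n_truncated = n_trunc
  )
  attr(ds, "truth") <- truth
  class(ds) <- c("clz_dataset", class(ds))
  ds
}

#' Ground-truth table of a simulated dataset
#'
#' Returns the per-subject generative draws (eta, individual and typical
#' parameters) recorded by [simulate_cohort()], for parameter-recovery and
#' shrinkage work.
#'
#' @param dataset A `clz_dataset` produced by [simulate_cohort()].
#' @return Tibble with one row per subject: `id`, `weight`, `zop`, `eta_cl`,
#'   `cl_tv`, `v_tv`, `cl_i`, `v_i`, `ka_i`.
#' @export
true_values <- function(dataset) {
  truth <- attr(dataset, "truth")
  if (is.null(truth)) {
    stop("dataset carries no ground truth (not produced by simulate_cohort())",
         call. = FALSE)
  }
  truth
}
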