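#' Monte Carlo simulation of one dosing scenario
#'
#' Draws `n_sim` subjects with `eta_cl ~ N(0, omega_cl^2)` at a fixed body
#' weight and zopiclone status, doses each at `dose_per_kg` mg/kg/day split
#' equally across the `interval_h` schedule, and computes the closed-form
#' steady-state trough for every draw. Troughs are "true" (residual-free)
#' concentrations by default; `residual = TRUE` adds the proportional error.
#' The probability of target attainment (`pta`) is the fraction of troughs in
#' the therapeutic window and `p_toxic` the fraction above the toxicity
#' threshold.
#'
#' @param pop A [pop_params()].
#' @param weight Body weight, kg.
#' @param dose_per_kg Daily dose, mg/kg/day.
#' @param zop Zopiclone flag, 0/1.
#' @param interval_h Dosing interval, h (daily dose split equally).
#' @param n_sim Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param target Therapeutic trough window, ng/mL.
#' @param toxic Toxicity trough threshold, ng/mL.
#' @param residual Add proportional residual error to the simulated troughs.
#' @return One-row tibble: scenario descriptors, `pta`, `p_toxic`, `p_below`
#'   (fraction under the window), `median_trough`, and the draws in a
#'   list-column `troughs`.
#' @examples
#' simulate_scenario(pop_params(), weight = 40, dose_per_kg = 10, zop = 0,
#'                   n_sim = 1000, seed = 1)
#' @export
simulate_scenario <- function(pop, weight, dose_per_kg, zop = 0,
                              interval_h = 12, n_sim = 1000, seed = 1L,
                              target = c(350, 800), toxic = 1000,
                              residual = FALSE) {
  stopifnot(inherits(pop, "clz_pop"), n_sim >= 1, dose_per_kg >= 0)
  set.seed(seed)
  eta <- stats::rnorm(n_sim, 0, pop$omega_cl)
  tv <- typical_params(pop, weight, zop)
  ind <- individual_params(tv[rep(1, n_sim), ], eta)
  dose_mg <- dose_per_kg * weight / (24 / interval_h)
  tr <- steady_state_trough(ind, dose_mg, interval_h)
  if (residual) {
    tr <- pmax(apply_residual(tr, stats::rnorm(n_sim, 0, pop$sigma_prop)), 0)
  }
  tibble::tibble(
    weight = weight, dose_per_kg = dose_per_kg, zop = zop,
    interval_h = interval_h, n_sim = n_sim,
    pta = mean(tr >= target[1] & tr <= target[2]),
    p_toxic = mean(tr > toxic),
    p_below = mean(tr < target[1]),
    median_trough = stats::median(tr),
    troughs = list(tr)
  )
}

#' Probability-of-target-attainment grid over weights and doses
#'
#' Runs [simulate_scenario()] for every (weight, dose) combination at a fixed
#' zopiclone status. Each scenario gets an independent sub-seed derived
#' deterministically from `seed`, so single scenarios can be reproduced in
#' isolation.
#'
#' @param pop A [pop_params()].
#' @param weights Weight grid, kg (published grid: 40, 60, 80, 100, 120).
#' @param doses Daily-dose grid, mg/kg/day (published grid: 1-10).
#' @param zop Zopiclone flag for the whole grid.
#' @inheritParams simulate_scenario
#' @return Tibble of class `clz_pta_grid`, one row per scenario.
#' @export
pta_grid <- function(pop, weights = c(40, 60, 80, 100, 120), doses = 1:10,
                     zop = 0, interval_h = 12, n_sim = 1000, seed = 1L,
                     target = c(350, 800), toxic = 1000, residual = FALSE) {
  stopifnot(length(weights) >= 1, length(doses) >= 1)
  grid <- tidyr::expand_grid(weight = weights, dose_per_kg = doses)
  out <- purrr::pmap(grid, function(weight, dose_per_kg) {
    sub_seed <- (seed * 1000003L +
                   as.integer(weight) * 1009L +
                   as.integer(round(dose_per_kg * 8))) %% 2147483647L
    simulate_scenario(pop, weight, dose_per_kg, zop = zop,
                      interval_h = interval_h, n_sim = n_sim,
                      seed = sub_seed, target = target, toxic = toxic,
                      residual = residual)
  }) |> dplyr::bind_rows()
  attr(out, "seed") <- seed
  class(out) <- c("clz_pta_grid", class(out))
  out
}

# Per-weight dose selection: maximize PTA subject to an optional toxicity
# cap; ties resolved toward the lower dose.
select_doses <- function(grid, p_toxic_cap = Inf) {
  grid |>
    dplyr::group_by(.data$weight) |>
    dplyr::filter(.data$p_toxic <= p_toxic_cap) |>
    dplyr::arrange(dplyr::desc(.data$pta), .data$dose_per_kg,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$weight)
}

#' Weight-banded dosing recommendation table
#'
#' Converts per-scenario Monte Carlo grids into a recommendation table: per
#' weight the dose maximizing the probability of target attainment is
#' selected (subject to an optional toxicity cap; ties go to the lower dose),
#' contiguous weights sharing a dose are merged into bands, and the maximum
#' toxicity-exceedance probability within each band is reported. Band edges
#' can instead be imposed (`bands = list(no_zop = c(...), zop = c(...))`) to
#' reproduce a published banding; each band then takes the dose selected at
#' the most common dose among its weights (majority, ties to lower dose).
#'
#' @param grid_no_zop,grid_zop [pta_grid()] results for the two groups
#'   (`grid_zop` optional).
#' @param p_toxic_cap Optional upper bound on `p_toxic` a selected dose must
#'   respect.
#' @param bands Optional list of imposed interior band edges per group.
#' @return Tibble of class `clz_rec`: `group`, `weight_lo`, `weight_hi`,
#'   `dose_per_kg`, `max_p_toxic_pct`.
#' @examples
#' g0 <- pta_grid(pop_params(), n_sim = 200, seed = 1)
#' recommend_doses(g0)
#' @export
recommend_doses <- function(grid_no_zop, grid_zop = NULL, p_toxic_cap = Inf,
                            bands = NULL) {
  if (!nrow(grid_no_zop)) stop("empty grid", call. = FALSE)
  one_group <- function(grid, group, edges = NULL) {
    sel <- select_doses(grid, p_toxic_cap)
    if (!nrow(sel)) stop("toxicity cap excludes every dose", call. = FALSE)
    w <- sel$weight
    if (is.null(edges)) {
      # discovery: contiguous weights sharing a dose become one band
      run <- cumsum(c(1, diff(sel$dose_per_kg) != 0))
      lo <- tapply(w, run, min)
      hi <- tapply(w, run, max)
      # band edges at midpoints between adjacent runs, covering [min, max]
      edges_full <- c(min(w),
                      (utils::head(hi, -1) + utils::tail(lo, -1)) / 2,
                      max(w))
      dose <- tapply(sel$dose_per_kg, run, function(x) x[1])
    } else {
      edges_full <- c(min(w), edges, max(w))
      band_of <- cut(w, breaks = edges_full, include.lowest = TRUE,
                     right = FALSE)
      levels_used <- levels(band_of)
      dose <- tapply(sel$dose_per_kg, band_of, function(x) {
        tb <- sort(table(x), decreasing = TRUE)
        as.numeric(names(tb)[1])
      })
      run <- as.integer(band_of)
    }
    n_band <- length(dose)
    edges_full <- unname(edges_full)
    out <- tibble::tibble(
      group = group,
      weight_lo = utils::head(edges_full, -1),
      weight_hi = utils::tail(edges_full, -1),
      dose_per_kg = as.numeric(dose)
    )
    # worst-case toxicity across the band's simulated weights at its dose
    out$max_p_toxic_pct <- vapply(seq_len(n_band), function(b) {
      ws <- w[run == b]
      rows <- grid$weight %in% ws & grid$dose_per_kg == out$dose_per_kg[b]
      round(100 * max(grid$p_toxic[rows]), 1)
    }, 0)
    out
  }
  res <- one_group(grid_no_zop, "no_zop", bands$no_zop)
  if (!is.null(grid_zop)) {
    res <- dplyr::bind_rows(res, one_group(grid_zop, "zop", bands$zop))
  }
  class(res) <- c("clz_rec", class(res))
  res
}
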