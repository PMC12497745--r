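test_that("CWRES are calibrated on self-simulated data", {
  ds <- simulate_cohort(final_pop(), design_spec(
    n_subjects = 100, p_zop = 0.25, seed = 81,
    n_trough_obs = 1, post_dose_sample_times = c(2, 6, 12)
  ))
  fit <- pk_fit(ds, effects = zop_effect(-0.254), se = FALSE)
  g <- gof(fit)
  n <- nrow(g)
  expect_identical(n, sum(ds$evid == 0))
  expect_true(all(is.finite(g$cwres)))
  expect_lt(abs(mean(g$cwres)), 3 / sqrt(n))
  expect_lt(abs(sd(g$cwres) - 1), 3 / sqrt(2 * n) + 0.05)
  # population predictions ignore eta; individual predictions track the data
  expect_gt(cor(g$ipred, g$dv), cor(g$pred, g$dv))
})

test_that("noise-free data give pred = ipred = dv", {
  gen <- pop_params(omega_cl = 0, sigma_prop = 1e-4)
  ds <- simulate_cohort(gen, design_spec(
    n_subjects = 12, p_zop = 0, seed = 82,
    n_trough_obs = 1, post_dose_sample_times = c(2, 6, 12)
  ))
  fit <- pk_fit(ds, init = pop_params(omega_cl = 0.05, sigma_prop = 0.05),
                se = FALSE)
  g <- gof(fit)
  expect_lt(max(abs(g$ipred - g$dv) / g$dv), 1e-3)
  expect_lt(max(abs(g$pred - g$dv) / g$dv), 1e-2)
})

test_that("without IIV, CWRES reduces to the proportional-error z-score", {
  gen <- pop_params(omega_cl = 0, sigma_prop = 0.15)
  ds <- simulate_cohort(gen, design_spec(
    n_subjects = 30, p_zop = 0, seed = 88,
    n_trough_obs = 1, post_dose_sample_times = c(2, 6, 12)
  ))
  fit <- pk_fit(ds, init = pop_params(omega_cl = 0.02, sigma_prop = 0.1),
                se = FALSE)
  # evaluate the diagnostic under the omega = 0 member of the model family:
  # the conditional covariance is then exactly diagonal and CWRES must be
  # the proportional-error z-score (dv - pred) / (sigma * pred)
  fit$pop$omega_cl <- 0
  fit$ebes$eta_cl <- rep(0, nrow(fit$ebes))
  g <- gof(fit)
  expect_equal(g$ipred, g$pred)
  z <- (g$dv - g$pred) / (fit$pop$sigma_prop * g$pred)
  expect_equal(g$cwres, z, tolerance = 1e-10)
})

test_that("VPC is reproducible, degenerate at n_sim = 1, and self-consistent", {
  ds <- simulate_cohort(final_pop(), design_spec(
    n_subjects = 80, p_zop = 0.25, seed = 83,
    n_trough_obs = 1, post_dose_sample_times = c(1, 3, 6, 9, 12)
  ))
  fit <- pk_fit(ds, effects = zop_effect(-0.254), se = FALSE)

  v1 <- vpc(fit, n_sim = 50, seed = 7)
  v2 <- vpc(fit, n_sim = 50, seed = 7)
  expect_identical(v1, v2)

  single <- vpc(fit, n_sim = 1, seed = 7)
  expect_equal(single$sim_lo, single$sim_hi)
  expect_equal(single$sim_lo, single$sim_med)

  v <- vpc(fit, n_sim = 300, seed = 11)
  expect_equal(sum(v$n_obs[v$percentile == 50]), sum(ds$evid == 0))
  inside <- mean(v$observed >= v$sim_lo & v$observed <= v$sim_hi)
  expect_gte(inside, 0.8) # self-simulated data: envelopes should cover
})

test_that("bootstrap bias formula reproduces published estimate/median pairs", {
  expect_equal(round(bias_pct(29.6, 29.4), 2), -0.68)
  expect_equal(round(bias_pct(308, 309), 2), 0.32)
  expect_equal(round(bias_pct(-0.254, -0.241), 2), -5.12)
  expect_equal(round(bias_pct(0.348, 0.342), 2), -1.72)
  expect_equal(round(bias_pct(0.257, 0.254), 2), -1.17)
})

test_that("bootstrap of a cloned cohort degenerates to the original fit", {
  one <- simulate_cohort(pop_params(sigma_prop = 0.08), design_spec(
    n_subjects = 1, seed = 84, n_trough_obs = 1,
    post_dose_sample_times = c(1, 4, 12)
  ))
  base <- as.data.frame(one)
  clones <- do.call(rbind, lapply(1:12, function(k) {
    b <- base
    b$id <- k
    b
  }))
  ds <- as_pk_dataset(clones)
  fit <- pk_fit(ds, se = FALSE,
                init = pop_params(omega_cl = 0.05, sigma_prop = 0.1))
  bt <- pk_bootstrap(fit, n_rep = 6, seed = 1)
  # identical subjects: every resample is the same dataset, so the
  # structural and residual parameters reproduce the original fit exactly;
  # omega is a boundary case (no between-subject signal), only its
  # "effectively zero" magnitude is stable
  s <- dplyr::filter(tidy(bt), term != "omega_cl")
  expect_equal(s$boot_median, s$estimate, tolerance = 1e-4)
  expect_lt(max((s$ci_hi - s$ci_lo) / abs(s$estimate)), 1e-4)
  expect_equal(s$bias_pct, rep(0, nrow(s)), tolerance = 1e-2)
  om <- dplyr::filter(tidy(bt), term == "omega_cl")
  expect_lt(om$boot_median, 0.01)
  expect_lt(om$estimate, 0.01)
})

test_that("bootstrap summaries respect their ordering invariants", {
  ds <- make_enriched(n = 24, seed = 85)
  fit <- pk_fit(ds, se = FALSE)
  bt <- pk_bootstrap(fit, n_rep = 12, seed = 2)
  s <- tidy(bt)
  expect_true(all(s$ci_lo <= s$boot_median + 1e-12))
  expect_true(all(s$boot_median <= s$ci_hi + 1e-12))
  expect_equal(s$bias_pct, bias_pct(s$estimate, s$boot_median))
  expect_true(bt$n_failed >= 0)
})

test_that("individual profiles pass through noise-free observations", {
  gen <- pop_params(omega_cl = 0.3, sigma_prop = 1e-4)
  ds <- simulate_cohort(gen, design_spec(
    n_subjects = 8, p_zop = 0, seed = 86,
    n_trough_obs = 1, post_dose_sample_times = c(2, 6, 12)
  ))
  fit <- pk_fit(ds, init = pop_params(omega_cl = 0.2, sigma_prop = 0.05),
                se = FALSE)
  pr <- individual_profiles(fit, n_grid = 51)
  obs <- dplyr::filter(pr, type == "obs")
  expect_identical(nrow(obs), sum(ds$evid == 0))
  # grid extends one dosing interval past the last observation
  curve_end <- max(pr$time[pr$type == "curve"])
  expect_equal(curve_end, max(obs$time) + 12)

  # a subject with eta > 0 clears faster: ipred below pred at the trough
  eb <- fit$ebes
  hi <- eb$id[which.max(eb$eta_cl)]
  expect_gt(max(eb$eta_cl), 0)
  sub <- dplyr::filter(pr, id == hi, type == "curve")
  at_end <- sub[which.max(sub$time), ]
  expect_lt(at_end$ipred, at_end$pred)
})

test_that("autoplot methods return ggplot objects", {
  ds <- make_enriched(n = 12, seed = 87)
  fit <- pk_fit(ds, se = FALSE)
  expect_s3_class(autoplot(gof(fit)), "ggplot")
  expect_s3_class(autoplot(vpc(fit, n_sim = 20, seed = 1)), "ggplot")
  expect_s3_class(autoplot(individual_profiles(fit, n_grid = 11)), "ggplot")
  g <- pta_grid(final_pop(), weights = c(40, 80), doses = c(4, 8),
                n_sim = 100, seed = 1)
  expect_s3_class(autoplot(g), "ggplot")
})
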