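test_that("sampled cohorts match the study demographics", {
  des <- design_spec(seed = 11)
  cov <- sample_cohort(des)
  expect_equal(nrow(cov), 81)
  expect_true(all(cov$weight >= 38 & cov$weight <= 120))
  # mean weight within 3 SE of 70.49 (SE = 13.53 / sqrt(81) = 1.5)
  expect_lt(abs(mean(cov$weight) - 70.49), 4.5)
  # zopiclone count within 3 binomial SDs of 8
  expect_lt(abs(sum(cov$zop) - 8), 3 * sqrt(81 * (8 / 81) * (73 / 81)))

  none <- sample_cohort(design_spec(n_subjects = 30, p_zop = 0, seed = 1))
  expect_true(all(none$zop == 0))
})

test_that("impossible weight truncation raises a configuration error", {
  expect_error(design_spec(weight_bounds = c(120, 38)), "increasing")
  des <- design_spec(weight_bounds = c(500, 700), seed = 1)
  expect_error(sample_cohort(des), "bounds")
})

test_that("identical seeds yield bit-identical datasets", {
  pop <- final_pop()
  des <- design_spec(n_subjects = 12, seed = 99,
                     post_dose_sample_times = c(2, 8))
  a <- simulate_cohort(pop, des)
  b <- simulate_cohort(pop, des)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(true_values(a), true_values(b))
})

test_that("with noise off, simulated troughs equal the analytic prediction", {
  pop <- pop_params(omega_cl = 0, sigma_prop = 1e-12)
  des <- design_spec(n_subjects = 8, seed = 3, p_zop = 0.5)
  ds <- simulate_cohort(pop, des)
  truth <- true_values(ds)
  obs <- ds[ds$evid == 0, ]
  for (i in truth$id) {
    ind <- tibble::tibble(
      cl_i = truth$cl_i[truth$id == i],
      v_i = truth$v_i[truth$id == i], ka_i = 1.3
    )
    dose_mg <- des$dose_per_kg * truth$weight[truth$id == i] / 2
    expect_equal(obs$dv[obs$id == i],
                 rep(steady_state_trough(ind, dose_mg, 12), 2),
                 tolerance = 1e-6)
  }
  expect_true(all(truth$eta_cl == 0))
})

test_that("median simulated trough matches the typical-subject trough", {
  # fixed 70 kg, no zopiclone: the eta -> trough map is monotone, so the
  # median trough is the typical trough (452.7 ng/mL at 280 mg q12h)
  pop <- final_pop()
  des <- design_spec(n_subjects = 2000, weight_mean = 70, weight_sd = 1e-6,
                     weight_bounds = c(69, 71), p_zop = 0, dose_per_kg = 8,
                     n_trough_obs = 1, seed = 21)
  ds <- simulate_cohort(pop, des)
  med <- median(ds$dv[ds$evid == 0])
  expect_lt(abs(med - 452.7) / 452.7, 0.05)
})

test_that("ground-truth table matches the generative draws", {
  pop <- final_pop()
  ds <- simulate_cohort(pop, design_spec(n_subjects = 3, seed = 5))
  truth <- true_values(ds)
  expect_equal(nrow(truth), 3)
  expect_equal(truth$id, 1:3)
  expect_equal(truth$cl_i, truth$cl_tv * exp(truth$eta_cl))
  expect_equal(truth$cl_tv,
               typical_params(pop, truth$weight, truth$zop)$cl)

  big <- true_values(
    simulate_cohort(pop, design_spec(n_subjects = 2000, seed = 6,
                                     n_trough_obs = 1))
  )
  expect_lt(abs(mean(big$eta_cl)), 3 * 0.348 / sqrt(2000))

  frozen <- true_values(
    simulate_cohort(pop_params(omega_cl = 0),
                    design_spec(n_subjects = 10, seed = 7))
  )
  expect_true(all(frozen$eta_cl == 0))

  # imported datasets carry no generative truth
  imported <- as_pk_dataset(as.data.frame(ds))
  expect_error(true_values(imported), "ground truth")
})

test_that("negative simulated observations are truncated and counted", {
  pop <- pop_params(sigma_prop = 0.9)
  ds <- simulate_cohort(pop, design_spec(n_subjects = 150, seed = 13,
                                         n_trough_obs = 2))
  meta <- attr(ds, "meta")
  obs <- ds$dv[ds$evid == 0]
  expect_true(all(obs >= 0))
  expect_gt(meta$n_truncated, 0)
  expect_equal(meta$n_truncated, sum(obs == 0))
})

test_that("explicit multi-dose emission agrees with the steady-state regimen", {
  pop <- pop_params(omega_cl = 0, sigma_prop = 1e-12)
  des_ss <- design_spec(n_subjects = 4, seed = 17, n_trough_obs = 1)
  des_ex <- design_spec(n_subjects = 4, seed = 17, n_trough_obs = 1,
                        n_days = 14)
  tr_ss <- simulate_cohort(pop, des_ss)
  tr_ex <- simulate_cohort(pop, des_ex)
  expect_equal(tr_ex$dv[tr_ex$evid == 0], tr_ss$dv[tr_ss$evid == 0],
               tolerance = 1e-3)
  expect_equal(sum(tr_ex$evid == 1), 4 * 28) # 14 days q12h, per subject
})
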