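test_that("typical parameters reproduce the final covariate model", {
  pop <- final_pop()
  tv <- typical_params(pop, weight = 70, zop = 0)
  expect_equal(tv$cl, 29.6)
  expect_equal(tv$v, 308)
  expect_equal(tv$ka, 1.3)

  # weight 40 kg under zopiclone: 29.6 * (40/70)^0.75 * 0.746
  tv40 <- typical_params(pop, weight = 40, zop = 1)
  expect_equal(tv40$cl, 14.51283, tolerance = 1e-6)
  expect_equal(tv40$v, 308 * 40 / 70)
})

test_that("reference-weight identity holds for arbitrary parameter sets", {
  set.seed(42)
  for (k in 1:10) {
    pop <- pop_params(
      cl_std = runif(1, 5, 60), v_std = runif(1, 50, 600),
      ka = runif(1, 0.3, 3), theta_zop = runif(1, -0.6, 0.6),
      omega_cl = runif(1, 0.05, 0.8), sigma_prop = runif(1, 0.05, 0.5)
    )
    tv <- typical_params(pop, weight = 70, zop = 0)
    expect_identical(tv$cl, pop$cl_std)
    expect_identical(tv$v, pop$v_std)
  }
})

test_that("clearance is monotone in weight and scales exactly with zopiclone", {
  pop <- final_pop()
  w <- seq(38, 120, by = 2)
  cl <- typical_params(pop, weight = w)$cl
  expect_true(all(diff(cl) > 0))
  tv0 <- typical_params(pop, weight = 55, zop = 0)
  tv1 <- typical_params(pop, weight = 55, zop = 1)
  expect_equal(tv1$cl / tv0$cl, 1 - 0.254)
  expect_equal(tv1$v, tv0$v)
})

test_that("degenerate covariate factors raise an invalid-model error", {
  expect_error(pop_params(theta_zop = -1.2), "theta_zop")
  bad <- covariate_effect("cl", "alb", kind = "linear", q = -2)
  expect_error(
    typical_params(final_pop(), 70, effects = list(bad),
                   extras = list(alb = 1)),
    "alb"
  )
  expect_error(covariate_effect("cl", "alb", kind = "power", q = 1), "s_m")
})

test_that("individual parameters follow the log-normal IIV model", {
  tv <- typical_params(final_pop(), weight = 70)
  expect_equal(individual_params(tv, 0)$cl_i, 29.6)
  up <- individual_params(tv, 0.348)
  dn <- individual_params(tv, -0.348)
  expect_equal(up$cl_i, 41.92047, tolerance = 1e-6)
  expect_equal(dn$cl_i, 20.90053, tolerance = 1e-6)
  expect_equal(up$cl_i * dn$cl_i, 29.6^2) # symmetry of the eta map
  expect_equal(up$v_i, tv$v)              # IIV on clearance only
  expect_equal(up$ka_i, tv$ka)
})

test_that("single-dose concentration matches the closed form and its limits", {
  ind <- individual_params(typical_params(final_pop(), 70), 0)
  doses <- data.frame(time = 0, amount = 560)
  expect_equal(predict_conc(ind, doses, 0), 0)
  expect_equal(predict_conc(ind, doses, 12), 619.6447, tolerance = 1e-5)

  # superposition of two doses is the sum of the shifted single-dose curves
  two <- data.frame(time = c(0, 12), amount = c(560, 560))
  expect_equal(
    predict_conc(ind, two, 18),
    predict_conc(ind, doses, 18) + predict_conc(ind, doses, 6)
  )

  # ka == ke degeneracy: analytic limit, no division blow-up
  v <- 308
  ind_deg <- tibble::tibble(cl_i = 1.3 * v, v_i = v, ka_i = 1.3)
  got <- predict_conc(ind_deg, data.frame(time = 0, amount = 100), 2)
  expect_equal(got, 1000 * 100 * 1.3 * 2 * exp(-1.3 * 2) / v,
               tolerance = 1e-6)
})

test_that("steady-state trough equals long superposition and is monotone in CL", {
  ind <- individual_params(typical_params(final_pop(), 70), 0)
  expect_equal(steady_state_trough(ind, 0, 12), 0)
  tr <- steady_state_trough(ind, 280, 12)
  expect_equal(tr, 452.6989, tolerance = 1e-5)
  expect_equal(tr, oracle_superposition_trough(29.6, 308, 1.3, 280, 12, 60),
               tolerance = 1e-3)

  # agreement with explicit multi-dose superposition after 20 doses (<0.1%)
  multi <- data.frame(time = seq(0, by = 12, length.out = 20), amount = 280)
  expect_equal(predict_conc(ind, multi, 20 * 12), tr, tolerance = 1e-3)

  # trough strictly decreases as individual clearance increases
  cls <- seq(10, 60, by = 5)
  trs <- steady_state_trough(
    tibble::tibble(cl_i = cls, v_i = 308, ka_i = 1.3), 280, 12
  )
  expect_true(all(diff(trs) < 0))

  # a repeating-regimen dose row gives the same trough as the closed form
  ss_row <- data.frame(time = 0, amount = 280, interval = 12)
  expect_equal(predict_conc(ind, ss_row, 36), tr, tolerance = 1e-9)
})

test_that("proportional residual model scales with the prediction", {
  expect_equal(apply_residual(400, 0), 400)
  expect_equal(apply_residual(400, 0.257), 502.8)
  expect_equal(apply_residual(0, 3), 0)
  expect_error(apply_residual(-1, 0), ">= 0")
})
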