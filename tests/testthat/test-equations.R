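# Surrogate predictor equations and their grid calibration.

test_that("E0 predictor inverts the Hertz law with analytic coefficients", {
  co <- analytic_seed_coefficients(nu = 0.45)
  # elastic half-space curve; R column set to the effective contact radius
  g <- ref_half_space()
  crv <- simulate_protocol(ref_material(1000, 100, 0.05), g,
                           ref_protocol(rate = 1000))
  d <- as.data.frame(extract_features(crv, smoothing_window = 1))
  d$R <- effective_radius(g)
  expect_equal(predict_E0(d, co), 1000,
               tolerance = exp(-10 / 0.05) * 0.1 + 1e-6)
  # linearity in F0
  d2 <- d
  d2$F0 <- 2 * d$F0
  expect_equal(predict_E0(d2, co), 2 * predict_E0(d, co))
  expect_error(predict_E0(within(d, u_max <- 0), co), "u_max")
})

test_that("tau predictor applies the half-decay identity", {
  co <- analytic_seed_coefficients()
  d <- data.frame(F1 = 1e-8, F0 = 9e-9, t1 = 0.5,
                  t_mid = 0.5 + 0.2 * log(2), u_max = 1e-6, R = 35e-6)
  expect_equal(predict_tau(d, co), 0.2)
  expect_error(predict_tau(within(d, t_mid <- 0.4), co), "t_mid")
  # noiseless surrogate features: exact recovery of the generating tau
  crv <- simulate_protocol(ref_material(1000, 100, 0.1), ref_microgel(),
                           ref_protocol(rate = 2000))
  f <- extract_features(crv, smoothing_window = 1)
  expect_equal(predict_tau(f, co), 0.1, tolerance = 1e-3)
})

test_that("E1 predictor has the right limits and monotonicity", {
  co <- analytic_seed_coefficients()
  d <- data.frame(F1 = 1e-8, F0 = 9e-9, t1 = 0.3, t_mid = 0.35,
                  u_max = 1e-6, R = 35e-6)
  p <- predict_E1(d, co, tau_pred = 0.1, E0_pred = 1000)
  # vanishing relaxation drives the prediction to zero
  d_small <- within(d, F0 <- F1 * (1 - 1e-9))
  expect_lt(predict_E1(d_small, co, 0.1, 1000), 1e-5 * p)
  # strictly increasing in the relative force drop
  d_big <- within(d, F0 <- 8e-9)
  expect_gt(predict_E1(d_big, co, 0.1, 1000), p)
  expect_error(predict_E1(within(d, F0 <- 1.1e-8), co, 0.1, 1000),
               "F0 must be below F1")
})

test_that("grid datasets are complete, deterministic and feature-consistent", {
  ds <- build_grid_dataset(small_grid(), sampling_rate = 1000)
  expect_identical(nrow(ds), 32L)
  expect_true(all(ds$F0 < ds$F1))
  expect_true(all(ds$t1 < ds$t_mid))
  # half-decay identity row by row, within one sampling interval
  expect_true(all(abs(ds$t_mid - ds$t1 - ds$tau_true * log(2)) < 1e-3))
  # triggers hit exactly
  expect_equal(ds$F1, ds$F1_level, tolerance = 1e-10)
  # determinism
  ds2 <- build_grid_dataset(small_grid(), sampling_rate = 1000)
  expect_identical(ds, ds2)
})

test_that("calibration on a sub-grid meets the analytic expectations", {
  ds <- build_grid_dataset(small_grid(), sampling_rate = 1000)
  cal <- calibrate_coefficients(ds, seed = 1,
                                control = list(pop_size = 20,
                                               max_iter = 60))
  # half-decay is exact in the surrogate: beta1 = 1/ln 2 within 1%
  expect_equal(cal$coefficients$beta1, 1 / log(2), tolerance = 0.01)
  # E0 power-law absorbs the double-contact geometry to a few percent
  expect_lt(cal$max_rel_err[["E0"]], 0.05)
  expect_gt(cal$coefficients$alpha2, 0)
  expect_gt(cal$coefficients$gamma2, 0)
  # per-run table is self-consistent with the reported maxima
  expect_equal(max(abs(cal$table$E0_pred - cal$table$E0_true) /
                     cal$table$E0_true), cal$max_rel_err[["E0"]])
  # determinism
  cal2 <- calibrate_coefficients(ds, seed = 1,
                                 control = list(pop_size = 20,
                                                max_iter = 60))
  expect_identical(cal$coefficients, cal2$coefficients)
})

test_that("calibration never does worse than the analytic seed", {
  ds <- build_grid_dataset(small_grid(), sampling_rate = 1000)
  cal <- calibrate_coefficients(ds, seed = 2,
                                control = list(pop_size = 20,
                                               max_iter = 60))
  seed_co <- analytic_seed_coefficients()
  seed_E0 <- predict_E0(ds[, c("F0", "u_max", "R")], seed_co)
  expect_lte(cal$mse[["E0"]], mean((seed_E0 - ds$E0_true)^2))
  seed_tau <- predict_tau(ds, seed_co)
  expect_lte(cal$mse[["tau"]], mean((seed_tau - ds$tau_true)^2))
})

test_that("error maps tabulate prediction errors and flag extrapolation", {
  ds <- build_grid_dataset(small_grid(), sampling_rate = 1000)
  cal <- calibrate_coefficients(ds, seed = 1,
                                control = list(pop_size = 20,
                                               max_iter = 60))
  em <- error_map(cal$coefficients, "E0",
                  fixed_conditions = list(E0 = 2000, ratio = 0.05,
                                          tau = 0.05, v = 5e-6),
                  F1_axis = c(2, 10) * 1e-9, R_axis = c(20, 50) * 1e-6,
                  sampling_rate = 1000)
  expect_identical(nrow(em), 4L)
  expect_true(all(em$true == 2000))
  expect_true(all(em$rel_err >= 0))
  expect_s3_class(attr(em, "worst"), "data.frame")
  # identity check against the calibration table at a shared grid point
  cell <- ds[ds$E0_true == 2000 & ds$ratio == 0.05 & ds$tau_true == 0.05 &
               ds$R == 20e-6 & ds$F1_level == 2e-9 & ds$v == 5e-6, ]
  tab_pred <- cal$table$E0_pred[as.integer(rownames(cell))]
  em_pred <- em$predicted[em$F1_N == 2e-9 & em$R_m == 20e-6]
  expect_equal(em_pred, tab_pred, tolerance = 1e-10)
  # out-of-range conditions warn about re-optimization
  expect_warning(
    error_map(cal$coefficients, "tau",
              fixed_conditions = list(E0 = 2000, E1 = 400, tau = 0.5,
                                      v = 5e-6),
              F1_axis = 2e-9, R_axis = 35e-6, sampling_rate = 1000),
    "re-optimization")
})
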