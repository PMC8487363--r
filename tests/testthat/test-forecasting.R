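test_that("offset, weighting and extrapolation primitives are exact", {
  # OS = alpha - observed gradient
  expect_equal(compute_test_offsets(0.4, 0.5, 0.2, 0.5), 0)
  expect_equal(compute_test_offsets(0, 0.4, 0.1, 1), -0.3)
  expect_equal(compute_test_offsets(c(1, 1), c(1, 2), c(0, 1), 1), c(0, 0))
  expect_error(compute_test_offsets(NA, 1, 0, 1), "non-finite")

  # beta = t(mu) %*% OS
  expect_equal(weighted_offset(diag(2), c(0.3, -0.1)), c(0.3, -0.1))
  expect_equal(weighted_offset(matrix(0, 3, 3), c(1, 2, 3)), rep(0, 3))
  expect_equal(weighted_offset(matrix(0.5, 2, 2), c(0.2, -0.2)), c(0, 0))
  expect_error(weighted_offset(diag(2), 1:3), "length")

  # forecast = last value + (alpha + beta) * dt
  expect_equal(forecast_value(0.5, 0.1, 0, 1), 0.6)
  expect_equal(forecast_value(0.5, 0.1, -0.1, 1), 0.5)
  expect_equal(forecast_value(0.4, 0.2, 0.05, 0.5), 0.525)
})

test_that("base-group assignment substitutes the suggested class's gradients", {
  base <- rbind("0" = c(0.1, 0.2), "1" = c(-0.3, -0.4))
  colnames(base) <- c("a", "b")
  r1 <- assign_base_gradient(c(0, 0), function(f) 1L, base)
  expect_identical(r1$class, 1L)
  expect_equal(unname(r1$alpha), c(-0.3, -0.4))
  r0 <- assign_base_gradient(c(0, 0), function(f) 0L, base)
  expect_equal(unname(r0$alpha), c(0.1, 0.2))
  # identical class rows: alpha independent of the suggestion
  base_sym <- rbind("0" = c(1, 2), "1" = c(1, 2))
  expect_equal(assign_base_gradient(0, function(f) 0L, base_sym)$alpha,
               assign_base_gradient(0, function(f) 1L, base_sym)$alpha)
})

test_that("base-group SVM separates classes and respects feature contracts", {
  sp <- separated_spec(n1 = 50, n0 = 50, nm = 2, noise_sd = 0.005,
                       gap = 0.3, seed = 41)
  ds <- generate_cohort(sp)
  feats <- base_group_features(ds)
  expect_identical(ncol(feats), 6L)   # 3 features per marker

  clf <- train_base_group_svm(ds)
  expect_equal(mean(predict(clf, ds) == ds$labels), 1)  # separable case

  # held-out accuracy at low noise
  ds_test <- generate_cohort({sp2 <- sp; sp2$seed <- 42L; sp2})
  expect_gte(mean(predict(clf, ds_test) == ds_test$labels), 0.95)
})

test_that("forecasts reproduce the generative model in the noiseless limit", {
  # zero-variance cohort: every forecast is exact class extrapolation
  sp <- linear_spec(n1 = 6, n0 = 8, nm = 2, dt = 0.5)
  ds <- generate_cohort(sp)
  model <- suppressWarnings(fit_weights_loo(ds))
  fc <- forecast_dataset(ds, model, "oracle")
  expect_equal(mae(fc), 0, tolerance = 1e-14)

  # coupled noiseless cohort with oracle base class: MAE below 1e-6
  spc <- coupled_spec(n1 = 20, n0 = 20, nm = 3, seed = 37)
  dsc <- generate_cohort(spc)
  mc <- fit_weights_loo(dsc)
  fcc <- forecast_dataset(dsc, mc, "oracle")
  expect_lt(mae(fcc), 1e-6)

  # ForecastSet invariant: predicted = y(t+dt) + (alpha + beta) dt, cellwise
  expect_equal(fcc$predicted,
               fcc$y_tdt + (fcc$alpha + fcc$beta) * fcc$dt,
               tolerance = 1e-14)
})

test_that("zero weights reduce the forecaster to base-gradient extrapolation", {
  sp <- coupled_spec(n1 = 8, n0 = 8, nm = 2, seed = 43, noise_sd = 0.05)
  ds <- generate_cohort(sp)
  model <- fit_weights_loo(ds)
  model$mu[] <- 0
  fc <- forecast_dataset(ds, model, "oracle")
  manual <- fc$y_tdt +
    model$base_gradients[as.character(ds$labels), ] * ds$dt
  expect_equal(unname(fc$predicted), unname(manual), tolerance = 1e-14)
})

test_that("forecasts ignore the base-group suggestion when classes share gradients", {
  sp <- cohort_spec(n_progressor = 8, n_stable = 8, n_markers = 2, dt = 0.5,
                    slope_progressor = c(-0.1, -0.2),
                    slope_stable = c(-0.1, -0.2),
                    subject_slope_sd = 0.1, noise_sd = 0.02,
                    baseline_ranges = cbind(c(1, 1), c(2, 2)), seed = 47)
  ds <- generate_cohort(sp)
  model <- fit_weights_loo(ds)
  # the empirical base gradients differ only by noise; equalize them so the
  # model is exactly class-symmetric, then the suggestion cannot matter
  model$base_gradients["0", ] <- model$base_gradients["1", ]
  all0 <- forecast_dataset(ds, model, function(f) 0L)
  all1 <- forecast_dataset(ds, model, function(f) 1L)
  expect_equal(all0$predicted, all1$predicted, tolerance = 1e-12)
})

test_that("forecast error grows with measurement noise", {
  maes <- vapply(c(0.01, 0.05, 0.2), function(noise) {
    sp <- coupled_spec(n1 = 40, n0 = 40, nm = 3, seed = 53,
                       noise_sd = noise)
    ds <- generate_cohort(sp)
    mae(forecast_dataset(ds, fit_weights_loo(ds), "oracle"))
  }, numeric(1))
  expect_true(all(diff(maes) >= -0.1 * maes[-length(maes)]))
})
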