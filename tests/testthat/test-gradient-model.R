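test_that("subject gradients are plain difference quotients", {
  expect_equal(compute_subject_gradient(0.4, 0.4, 2), 0)
  expect_equal(compute_subject_gradient(0.2, 0.5, 0.5), 0.6)
  expect_equal(compute_subject_gradient(0.5, 0.2, 1.0), -0.3)
  expect_equal(compute_subject_gradient(c(0, 1), c(1, 3), 0.5), c(2, 4))
  expect_error(compute_subject_gradient(0, 1, 0), "dt")
})

test_that("base gradients average first-interval change per class", {
  # one progressor with change 0.1 over dt = 0.5 -> 0.2/yr
  ds <- tiny_two_subject(c(0.2, 0.3, 0.4), c(0.5, 0.5, 0.5), dt = 0.5)
  base <- compute_base_gradients(ds)
  expect_equal(unname(base["1", 1]), 0.2)
  expect_equal(unname(base["0", 1]), 0)

  # two stable subjects with interval changes +0.1 and +0.3 over dt = 1
  arr <- array(0, dim = c(3, 1, 3))
  arr[1, 1, ] <- c(1, 1.05, 1.1)         # the required progressor
  arr[2, 1, ] <- c(1, 1.1, 1.2)
  arr[3, 1, ] <- c(2, 2.3, 2.6)
  ds2 <- make_dataset(arr, labels = c(1L, 0L, 0L), dt = 1)
  expect_equal(unname(compute_base_gradients(ds2)["0", 1]), 0.2)

  # flat trajectories give zero gradients for every class and marker
  flat <- make_dataset(array(3, dim = c(4, 2, 3)),
                       labels = c(1L, 1L, 0L, 0L))
  expect_true(all(compute_base_gradients(flat) == 0))
})

test_that("offset systems subtract observed gradients from base gradients", {
  # class-1 subject: base 0.2, first-interval gradient 0.5, second 0.1
  ds <- tiny_two_subject(c(1, 1.5, 1.6), c(1, 1, 1), dt = 1)
  base <- rbind("0" = 0, "1" = 0.2)
  colnames(base) <- ds$marker_ids
  sys <- build_offset_system(ds, base)
  expect_equal(unname(sys$A[1, 1]), -0.3)
  expect_equal(unname(sys$B[1, 1]), 0.1)

  # a subject matching its class base gradients has a zero row in A and B
  expect_equal(unname(sys$A[2, 1]), 0)
  expect_equal(unname(sys$B[2, 1]), 0)

  # noiseless coupled cohort: measured system satisfies B = A mu* exactly
  sp <- coupled_spec(n1 = 15, n0 = 15, nm = 3, seed = 23)
  dsc <- generate_cohort(sp)
  sysc <- build_offset_system(dsc, compute_base_gradients(dsc))
  expect_lt(max(abs(sysc$A %*% sp$coupling_matrix - sysc$B)), 1e-12)

  # training requires complete trajectories
  arr <- array(1, dim = c(2, 1, 3)); arr[1, 1, 3] <- NA
  dsi <- longitudinal_dataset(arr, labels = c(1L, 0L), dt = 1,
                              require_complete = FALSE)
  expect_error(build_offset_system(dsi, base), "third")
})

test_that("least-squares weights match closed forms and the pseudoinverse", {
  # identity system returns the target column directly
  mu <- solve_weights(list(A = diag(2), B = cbind(c(2, 3), c(0, 1))))
  expect_equal(unname(mu[, 1]), c(2, 3))

  # inconsistent single-column system: least-squares mean
  mu2 <- solve_weights(list(A = matrix(1, 2, 1), B = matrix(c(1, 3), 2, 1)))
  expect_equal(unname(mu2[1, 1]), 2)

  # random well-conditioned systems against the independent pseudoinverse
  set.seed(99)
  for (i in 1:25) {
    n <- sample(10:50, 1); N <- sample(2:10, 1)
    A <- matrix(rnorm(n * N), n, N)
    B <- matrix(rnorm(n * N), n, N)
    expect_lt(max(abs(solve_weights(list(A = A, B = B)) -
                        MASS::ginv(A) %*% B)), 1e-8)
  }

  # rank-deficient system: warning + minimum-norm solution
  A <- cbind(1:4, 2 * (1:4))
  B <- cbind(1:4, 0)
  expect_warning(mu3 <- solve_weights(list(A = A, B = B)), "rank-deficient")
  expect_equal(mu3, MASS::ginv(A) %*% B, tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(solve_weights(list(A = matrix(NA_real_, 1, 1),
                                  B = matrix(1, 1, 1))), "non-finite")
  expect_error(solve_weights(list(A = matrix(0, 0, 1),
                                  B = matrix(0, 0, 1))), "empty")
})

test_that("LOO-averaged weights recover a known coupling matrix", {
  # exact recovery on a noiseless coupled cohort
  sp <- coupled_spec(n1 = 25, n0 = 25, nm = 3, seed = 11)
  ds <- generate_cohort(sp)
  model <- fit_weights_loo(ds)
  expect_lt(max(abs(coef(model) - sp$coupling_matrix)), 1e-6)
  expect_identical(model$n_loo_folds, 50L)
  expect_identical(model$marker_ids, ds$marker_ids)

  # n = 3 subjects -> exactly 3 folds averaged (tiny folds are collinear, so
  # the minimum-norm path kicks in with a warning)
  sp3 <- coupled_spec(n1 = 2, n0 = 2, nm = 2, seed = 2)
  ds3 <- subset_dataset(generate_cohort(sp3), subjects = c(1, 3, 4))
  m3 <- suppressWarnings(fit_weights_loo(ds3))
  expect_identical(m3$n_loo_folds, 3L)
  expect_error(fit_weights_loo(subset_dataset(ds3, subjects = 1:2)),
               "at least 3")

  # recompute_base = TRUE skips single-class folds with a warning
  w <- capture_warnings(m4 <- fit_weights_loo(ds3, recompute_base = TRUE))
  expect_match(w, "skipped", all = FALSE)
  expect_identical(m4$n_loo_folds, 2L)
})

test_that("weights are invariant to the follow-up spacing convention", {
  # same readings at spacing dt vs k*dt: gradients rescale by 1/k on both
  # sides of the offset system, so mu is unchanged
  sp <- coupled_spec(n1 = 10, n0 = 10, nm = 3, dt = 0.5, seed = 29)
  ds <- generate_cohort(sp)
  ds_stretched <- longitudinal_dataset(ds$values, labels = ds$labels,
                                       dt = 2, subject_ids = ds$subject_ids,
                                       marker_ids = ds$marker_ids)
  m1 <- fit_weights_loo(ds)
  m2 <- fit_weights_loo(ds_stretched)
  expect_equal(coef(m1), coef(m2), tolerance = 1e-10)
  expect_equal(m1$base_gradients, 4 * m2$base_gradients, tolerance = 1e-12)
})
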