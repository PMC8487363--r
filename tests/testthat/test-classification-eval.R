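test_that("trajectory features concatenate the three visits per marker", {
  ds <- generate_cohort(cohort_spec(n_progressor = 3, n_stable = 3,
                                    n_markers = 2, seed = 61))
  tf <- build_trajectory_features(ds)
  expect_identical(ncol(tf$features), 6L)   # 3 visits x 2 markers
  expect_equal(unname(tf$features[1, 1:3]), unname(ds$values[1, 1, ]))
  expect_identical(tf$labels, ds$labels)

  # forecast mode replaces only the third-visit slots
  model <- fit_weights_loo(ds)
  fc <- forecast_dataset(ds, model, "oracle")
  tff <- build_trajectory_features(ds, forecast = fc)
  expect_equal(unname(tff$features[, c(3, 6)]), unname(fc$predicted))
  expect_equal(tff$features[, c(1, 2, 4, 5)], tf$features[, c(1, 2, 4, 5)])

  # incomplete trajectories are refused
  arr <- ds$values; arr[1, , 3] <- NA
  dsi <- longitudinal_dataset(arr, ds$labels, ds$dt,
                              require_complete = FALSE)
  expect_error(build_trajectory_features(dsi), "incomplete|missing")
})

test_that("trajectory SVM separates a linearly separable toy set", {
  set.seed(67)
  train_x <- rbind(matrix(3 + rnorm(40, sd = 0.2), 10, 4),
                   matrix(-3 + rnorm(40, sd = 0.2), 10, 4))
  train_y <- c(rep(1L, 10), rep(0L, 10))
  test_x <- rbind(matrix(4, 2, 4), matrix(-4, 2, 4))
  res <- classify_trajectories(train_x, train_y, test_x)
  expect_identical(res$labels, c(1L, 1L, 0L, 0L))
  # deeper in the positive half-space scores strictly larger
  test_deep <- rbind(matrix(3, 1, 4), matrix(6, 1, 4))
  res2 <- classify_trajectories(train_x, train_y, test_deep)
  expect_gt(res2$scores[2], res2$scores[1])
  expect_error(classify_trajectories(train_x, rep(1L, 20), test_x),
               "both classes")
})

test_that("rank AUC equals the brute-force pairwise count", {
  brute_auc <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  set.seed(71)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc_rank(labels, scores), brute_auc(labels, scores))
  }
  expect_warning(one <- auc_rank(c(1, 1), c(0.2, 0.3)), "one class")
  expect_true(is.na(one))
})

test_that("confusion metrics follow hand-computed counts", {
  # perfect separation
  m <- evaluate_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0),
                        scores = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  # one missed progressor
  m2 <- evaluate_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 1)

  # MAE on matched values, reported as percent
  m3 <- evaluate_metrics(c(1, 0), c(1, 0),
                         predicted_values = c(0.5, 0.6),
                         observed_values = c(0.5, 0.5))
  expect_equal(m3$mae_percent, 5)
  expect_equal(evaluate_metrics(c(1, 0), c(1, 0),
                                predicted_values = c(0.1, 0.2),
                                observed_values = c(0.1, 0.2))$mae_percent, 0)

  # accuracy decomposes into the class-weighted mean of sens/spec
  set.seed(73)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.4))
    pred <- rbinom(n, 1, 0.5)
    m <- evaluate_metrics(truth, pred)
    n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
    expect_equal(m$accuracy,
                 (m$sensitivity * n_pos + m$specificity * n_neg) / n)
  }
})

test_that("stratified folds keep both classes with near-equal sizes", {
  ds <- generate_cohort(cohort_spec(n_progressor = 49, n_stable = 70,
                                    n_markers = 2, seed = 79))
  res <- run_nested_cv(ds, run_config(mode = "gt", max_subset = 1, seed = 7))
  folds <- res$folds
  for (f in 1:5) {
    expect_true(all(c(0L, 1L) %in% ds$labels[folds == f]))
  }
  per_class <- table(ds$labels, folds)
  expect_lte(max(per_class["1", ]) - min(per_class["1", ]), 1)
  expect_lte(max(per_class["0", ]) - min(per_class["0", ]), 1)

  # too few subjects per class for 5 folds
  small <- generate_cohort(cohort_spec(n_progressor = 4, n_stable = 20,
                                       n_markers = 2, seed = 80))
  expect_error(run_nested_cv(small, run_config(mode = "gt")), "fewer subjects")
})

test_that("best-model selection maximizes forecast AUC, ties to smaller", {
  rep <- data.frame(mode = "forecast", subset_size = 1:3, fold = 0L,
                    mae_percent = 1, auc = c(0.7, 0.9, 0.9),
                    accuracy = 0.8, sensitivity = 0.8, specificity = 0.8,
                    n = 10)
  best <- select_best_model(rep)
  expect_identical(best$subset_size, 2L)
  expect_identical(select_best_model(rep[1, ])$subset_size, 1L)
  rep_mono <- transform(rep, auc = c(0.5, 0.6, 0.7))
  expect_identical(select_best_model(rep_mono)$subset_size, 3L)
})

test_that("nested CV report is internally consistent", {
  sp <- separated_spec(n1 = 25, n0 = 30, nm = 4, seed = 83)
  ds <- generate_cohort(sp)
  res <- run_nested_cv(ds, run_config(max_subset = 3, seed = 5))
  rep <- res$report
  expect_setequal(unique(rep$mode), c("forecast", "gt"))
  # one row per mode x size x fold plus one aggregate per mode x size
  expect_identical(nrow(rep), 2L * 3L * 6L)
  # ground-truth mode has zero forecast error by construction
  expect_true(all(rep$mae_percent[rep$mode == "gt"] == 0))
  # metrics live in [0, 1]
  for (col in c("auc", "accuracy", "sensitivity", "specificity"))
    expect_true(all(rep[[col]] >= 0 & rep[[col]] <= 1, na.rm = TRUE))
  # aggregate rows are the fold means
  for (mode in c("forecast", "gt")) {
    sub <- rep[rep$mode == mode & rep$subset_size == 2, ]
    expect_equal(sub$auc[sub$fold == 0], mean(sub$auc[sub$fold > 0]))
    expect_equal(sub$mae_percent[sub$fold == 0],
                 mean(sub$mae_percent[sub$fold > 0]))
  }
  # per-subject counts: each fold covers the held-out subjects once
  expect_equal(sum(rep$n[rep$mode == "gt" & rep$subset_size == 1 &
                           rep$fold > 0]), 55)
})
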