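#' Trajectory feature matrix for classification
#'
#' Per subject, the concatenation of all three visit values over the marker
#' subset (length `3N`).  With a `forecast` argument the third-visit slots
#' are taken from the forecast rather than the observations, producing the
#' features the pipeline classifies at test time.
#'
#' @param ds a [longitudinal_dataset()].
#' @param markers marker subset (ids or indices; default all).
#' @param forecast optional [forecast_dataset()] result supplying the
#'   third-visit values (its markers must match the subset).
#' @return list with `features` (n x 3N matrix) and `labels`.
#' @export
build_trajectory_features <- function(ds, markers = NULL, forecast = NULL) {
  stopifnot(inherits(ds, "longitudinal_dataset"))
  mi <- resolve_index(markers, ds$marker_ids, "marker")
  n <- n_subjects(ds)
  N <- length(mi)
  third <- matrix(ds$values[, mi, 3], n, N)
  if (!is.null(forecast)) {
    stopifnot(inherits(forecast, "forecast_set"))
    if (!identical(forecast$marker_ids, ds$marker_ids[mi]))
      stop("forecast markers do not match the requested subset")
    if (!identical(forecast$subject_ids, ds$subject_ids))
      stop("forecast subjects do not match the dataset")
    third <- forecast$predicted
  }
  if (anyNA(third))
    stop("incomplete trajectory: third visit missing for subject(s) ",
         paste(ds$subject_ids[apply(is.na(third), 1, any)], collapse = ", "))
  feats <- do.call(cbind, lapply(seq_len(N), function(k)
    cbind(ds$values[, mi[k], 1], ds$values[, mi[k], 2], third[, k])))
  colnames(feats) <- as.vector(vapply(ds$marker_ids[mi], function(id)
    paste0(id, c("_t0", "_t1", "_t2")), character(3)))
  rownames(feats) <- ds$subject_ids
  list(features = feats, labels = ds$labels)
}

#' Linear-SVM trajectory classification
#'
#' Fits a linear-kernel maximum-margin classifier on training trajectories
#' and scores test trajectories.  Decision scores are signed margin
#' distances oriented so that larger means more progressor-like, suitable
#' for ROC analysis.
#'
#' @param train_features,train_labels training trajectories and 0/1 labels
#'   (both classes required).
#' @param test_features trajectories to classify.
#' @param cost SVM regularization constant C.
#' @return list with `labels` (0/1 predictions) and `scores`.
#' @export
classify_trajectories <- function(train_features, train_labels, test_features,
                                  cost = 1) {
  if (length(unique(train_labels)) < 2L)
    stop("trajectory classifier needs both classes in the training set")
  fit <- fit_linear_svm(as.matrix(train_features), train_labels, cost = cost)
  predict_linear_svm(fit, as.matrix(test_features))
}

#' Rank-statistic area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a random positive outscores a
#' random negative, with ties counted half.
#'
#' @param labels 0/1 truth.
#' @param scores continuous scores, larger = more positive-like.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if only one class is
#'   present.
#' @export
auc_rank <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification and forecasting metrics for one evaluation
#'
#' Computes the standard report row: mean absolute forecast error (on the
#' normalized scale, reported x100 as a percentage), rank-statistic AUC of
#' the decision scores, and accuracy / sensitivity / specificity from the
#' confusion matrix with progressors (label 1) as the positive class.
#'
#' @param labels_true,labels_pred 0/1 truth and predictions.
#' @param scores decision scores for AUC (optional; `NA` AUC if absent).
#' @param predicted_values,observed_values matched arrays of forecast and
#'   observed marker values for the MAE (optional).
#' @return a one-row `data.frame` with columns `mae_percent`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `n`.
#' @export
evaluate_metrics <- function(labels_true, labels_pred, scores = NULL,
                             predicted_values = NULL, observed_values = NULL) {
  labels_true <- as.integer(labels_true)
  labels_pred <- as.integer(labels_pred)
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must be conformable")
  tp <- sum(labels_true == 1L & labels_pred == 1L)
  tn <- sum(labels_true == 0L & labels_pred == 0L)
  n_pos <- sum(labels_true == 1L)
  n_neg <- sum(labels_true == 0L)
  mae_percent <- NA_real_
  if (!is.null(predicted_values)) {
    if (is.null(observed_values) ||
        length(predicted_values) != length(observed_values))
      stop("`predicted_values` and `observed_values` must be conformable")
    mae_percent <- 100 * mean(abs(predicted_values - observed_values))
  }
  data.frame(
    mae_percent = mae_percent,
    auc = if (is.null(scores)) NA_real_ else auc_rank(labels_true, scores),
    accuracy = (tp + tn) / length(labels_true),
    sensitivity = if (n_pos > 0L) tp / n_pos else NA_real_,
    specificity = if (n_neg > 0L) tn / n_neg else NA_real_,
    n = length(labels_true))
}

#' Configuration of a nested cross-validation run
#'
#' @param folds number of stratified outer folds (default 5).
#' @param max_subset largest marker-subset size to evaluate (default: all
#'   markers).
#' @param seed integer seed governing the fold split (all randomness in a
#'   run flows from it).
#' @param mode `"both"` (default), `"forecast"` or `"gt"` (ground-truth
#'   benchmark, which classifies observed trajectories and thus bypasses
#'   forecasting).
#' @param normalization `"cohort"` (per-marker maxima of the full dataset
#'   before the split, the method's own convention, default) or
#'   `"within_train"` (leakage-free: training-fold maxima applied to the
#'   test fold).
#' @param ttest `"student"` or `"welch"` for marker ranking.
#' @param svm_c regularization constant for both SVMs.
#' @param oracle_base_class if `TRUE`, true labels replace the base-group
#'   SVM's suggestion (diagnostic use).
#' @param recompute_base passed to [fit_weights_loo()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(folds = 5, max_subset = NULL, seed = 1L,
                       mode = c("both", "forecast", "gt"),
                       normalization = c("cohort", "within_train"),
                       ttest = c("student", "welch"),
                       svm_c = 1, oracle_base_class = FALSE,
                       recompute_base = FALSE) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  ttest <- match.arg(ttest)
  if (!is.numeric(folds) || folds != round(folds) || folds < 2)
    stop("`folds` must be an integer >= 2")
  if (!is.null(max_subset) &&
      (!is.numeric(max_subset) || max_subset != round(max_subset) ||
       max_subset < 1))
    stop("`max_subset` must be a positive integer")
  if (!is.numeric(seed) || seed != round(seed)) stop("`seed` must be integer")
  if (!is.numeric(svm_c) || svm_c <= 0) stop("`svm_c` must be positive")
  structure(list(folds = as.integer(folds),
                 max_subset = if (is.null(max_subset)) NULL
                              else as.integer(max_subset),
                 seed = as.integer(seed), mode = mode,
                 normalization = normalization, ttest = ttest,
                 svm_c = svm_c,
                 oracle_base_class = isTRUE(oracle_base_class),
                 recompute_base = isTRUE(recompute_base)),
            class = "run_config")
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin, so per-class fold sizes differ by at most one.
stratified_folds <- function(labels, k, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(labels))
  for (lab in c(1L, 0L)) {
    idx <- which(labels == lab)
    if (length(idx) < k)
      stop("class ", lab, " has fewer subjects (", length(idx),
           ") than folds (", k, ")")
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Nested cross-validated forecasting-and-classification pipeline
#'
#' The full evaluation loop: markers are ranked by baseline t-test
#' significance; for every incremental subset size and every stratified
#' outer fold, the gradient-offset model and base-group SVM are fitted on
#' the training fold, the test fold's third visits are forecast, and a
#' trajectory SVM (trained on the training fold's observed trajectories)
#' classifies the forecast-completed test trajectories.  The ground-truth
#' mode runs the same loop on fully observed trajectories, bypassing
#' forecasting, and serves as the benchmark ceiling.
#'
#' @param ds a complete [longitudinal_dataset()] with >= 10 subjects.
#' @param config a [run_config()].
#' @return an object of class `nested_cv_report`: list with `report` (one
#'   row per mode x subset size x fold, plus fold-averaged rows with
#'   `fold = 0`, which also carry the fold-pooled AUC), `ranking`, `folds`
#'   and `config`.
#' @export
run_nested_cv <- function(ds, config = run_config()) {
  stopifnot(inherits(ds, "longitudinal_dataset"),
            inherits(config, "run_config"))
  n <- n_subjects(ds)
  if (n < 10L) stop("nested cross-validation needs at least 10 subjects")
  nm <- length(ds$marker_ids)
  max_subset <- min(config$max_subset %||% nm, nm)
  modes <- if (config$mode == "both") c("forecast", "gt") else config$mode

  if (config$normalization == "cohort") ds_work <- normalize_dataset(ds)
  else ds_work <- ds
  ranking <- rank_markers(ds_work, method = config$ttest)
  subsets <- build_subsets(ranking, max_subset)

  fold_id <- stratified_folds(ds_work$labels, config$folds, config$seed)

  rows <- list()
  score_pool <- list()
  for (size in seq_along(subsets)) {
    markers <- subsets[[size]]
    for (f in seq_len(config$folds)) {
      train_idx <- which(fold_id != f)
      test_idx <- which(fold_id == f)
      if (length(unique(ds_work$labels[train_idx])) < 2L ||
          length(unique(ds_work$labels[test_idx])) < 2L)
        stop("fold ", f, " lost a class; use fewer folds or more subjects")
      train <- subset_dataset(ds_work, subjects = train_idx, markers = markers)
      test <- subset_dataset(ds_work, subjects = test_idx, markers = markers)
      if (config$normalization == "within_train") {
        sc <- marker_scales(train)
        train <- normalize_dataset(train, scale = sc)
        test <- normalize_dataset(test, scale = sc)
      }

      feats_train <- build_trajectory_features(train)
      traj_train_labels <- train$labels

      need_forecast <- "forecast" %in% modes
      if (need_forecast) {
        model <- fit_weights_loo(train, recompute_base = config$recompute_base)
        classifier <- if (config$oracle_base_class) "oracle"
                      else train_base_group_svm(train, cost = config$svm_c)
        fc <- forecast_dataset(test, model, classifier)
      }

      for (mode in modes) {
        if (mode == "forecast") {
          feats_test <- build_trajectory_features(test, forecast = fc)
          pred_vals <- fc$predicted
          obs_vals <- fc$observed
        } else {
          feats_test <- build_trajectory_features(test)
          pred_vals <- obs_vals <- matrix(test$values[, , 3],
                                          n_subjects(test),
                                          length(test$marker_ids))
        }
        cls <- classify_trajectories(feats_train$features, traj_train_labels,
                                     feats_test$features,
                                     cost = config$svm_c)
        row <- evaluate_metrics(test$labels, cls$labels, cls$scores,
                                pred_vals, obs_vals)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(mode = mode, subset_size = size, fold = f,
                     stringsAsFactors = FALSE), row)
        key <- paste(mode, size)
        score_pool[[key]] <- rbind(
          score_pool[[key]],
          data.frame(label = test$labels, score = cls$scores))
      }
    }
  }
  report <- do.call(rbind, rows)

  # fold-averaged rows (fold = 0); pooled AUC across folds as an extra column
  agg <- list()
  for (mode in modes) {
    for (size in seq_along(subsets)) {
      sub <- report[report$mode == mode & report$subset_size == size, ]
      pool <- score_pool[[paste(mode, size)]]
      agg[[length(agg) + 1L]] <- data.frame(
        mode = mode, subset_size = size, fold = 0L,
        mae_percent = mean(sub$mae_percent),
        auc = mean(sub$auc),
        accuracy = mean(sub$accuracy),
        sensitivity = mean(sub$sensitivity),
        specificity = mean(sub$specificity),
        n = sum(sub$n),
        stringsAsFactors = FALSE)
      agg[[length(agg)]]$auc_pooled <- auc_rank(pool$label, pool$score)
    }
  }
  report$auc_pooled <- NA_real_
  report <- rbind(report, do.call(rbind, agg))
  rownames(report) <- NULL

  structure(list(report = report, ranking = ranking, folds = fold_id,
                 config = config, marker_ids = ds$marker_ids,
                 subsets = subsets),
            class = "nested_cv_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold-averaged rows of a nested CV report
#'
#' @param x a [run_nested_cv()] result.
#' @param mode restrict to one mode (optional).
#' @return the `fold = 0` aggregate rows.
#' @export
aggregate_report <- function(x, mode = NULL) {
  stopifnot(inherits(x, "nested_cv_report"))
  out <- x$report[x$report$fold == 0L, ]
  if (!is.null(mode)) out <- out[out$mode == mode, ]
  rownames(out) <- NULL
  out
}

#' Best marker-subset size by forecast-mode AUC
#'
#' Picks the subset size whose fold-averaged forecast-mode AUC is maximal;
#' ties resolve to the smallest subset.  Falls back to ground-truth rows if
#' the report holds no forecast mode.
#'
#' @param x a [run_nested_cv()] result (or its `report` data.frame).
#' @return list with `subset_size` and the corresponding aggregate `metrics`
#'   row.
#' @export
select_best_model <- function(x) {
  report <- if (inherits(x, "nested_cv_report")) x$report else x
  agg <- report[report$fold == 0L, ]
  if (!nrow(agg)) stop("report has no aggregate rows")
  mode <- if ("forecast" %in% agg$mode) "forecast" else agg$mode[1]
  agg <- agg[agg$mode == mode, ]
  agg <- agg[order(agg$subset_size), ]
  best <- which.max(agg$auc)    # first maximum = smallest subset on ties
  list(subset_size = agg$subset_size[best], metrics = agg[best, ])
}

#' @export
print.nested_cv_report <- function(x, ...) {
  cat("Nested CV report: ", x$config$folds, "-fold outer loop, subset sizes 1..",
      max(x$report$subset_size), ", modes: ",
      paste(unique(x$report$mode), collapse = ", "), "\n", sep = "")
  best <- select_best_model(x)
  cat("Best model (fold-averaged forecast AUC): subset size ",
      best$subset_size, ", AUC = ", signif(best$metrics$auc, 4),
      ", MAE = ", signif(best$metrics$mae_percent, 4), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.nested_cv_report <- function(object, ...) {
  cat("Fold-averaged metrics per mode and subset size:\n")
  agg <- aggregate_report(object)
  num <- vapply(agg, is.numeric, logical(1))
  agg[num] <- lapply(agg[num], function(v) signif(v, 4))
  print(agg, row.names = FALSE)
  invisible(object)
}

#' @export
plot.nested_cv_report <- function(x, ...) {
  agg_f <- aggregate_report(x, "forecast")
  agg_g <- aggregate_report(x, "gt")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (nrow(agg_f)) {
    graphics::plot(agg_f$subset_size, agg_f$mae_percent, type = "b",
                   xlab = "subset size", ylab = "forecast MAE (%)",
                   main = "Forecast error")
  }
  ylim <- range(c(agg_f$auc, agg_g$auc), na.rm = TRUE)
  graphics::plot(agg_f$subset_size %||% agg_g$subset_size,
                 (if (nrow(agg_f)) agg_f else agg_g)$auc, type = "b",
                 ylim = ylim, xlab = "subset size", ylab = "fold-averaged AUC",
                 main = "Classification")
  if (nrow(agg_g) && nrow(agg_f)) {
    graphics::lines(agg_g$subset_size, agg_g$auc, type = "b", lty = 2,
                    pch = 2)
    graphics::legend("bottomright", legend = c("forecast", "ground truth"),
                     lty = c(1, 2), pch = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Write a nested CV report as CSV
#'
#' One row per (mode, subset size, fold), fold 0 holding the fold-averaged
#' aggregates; numbers are written at full precision so identical runs
#' produce byte-identical files.
#'
#' @param x a [run_nested_cv()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "nested_cv_report"))
  df <- x$report
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
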