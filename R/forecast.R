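#' Known-visit feature matrix for base-group classification
#'
#' Per subject and marker: the first two visit values and their annual
#' change, concatenated over the marker subset (feature dimension
#' `3 * |markers|`).  Used both to train the base-group classifier and to
#' score new subjects from their first two visits.
#'
#' @param ds a [longitudinal_dataset()] (third visits not needed).
#' @param markers marker subset (ids or indices; default all).
#' @return numeric matrix `n_subjects x 3N`.
#' @export
base_group_features <- function(ds, markers = NULL) {
  stopifnot(inherits(ds, "longitudinal_dataset"))
  mi <- resolve_index(markers, ds$marker_ids, "marker")
  n <- n_subjects(ds)
  x1 <- matrix(ds$values[, mi, 1], n, length(mi))
  x2 <- matrix(ds$values[, mi, 2], n, length(mi))
  g <- (x2 - x1) / ds$dt
  feats <- do.call(cbind, lapply(seq_along(mi), function(k)
    cbind(x1[, k], x2[, k], g[, k])))
  colnames(feats) <- as.vector(vapply(ds$marker_ids[mi], function(id)
    paste0(id, c("_t0", "_t1", "_grad")), character(3)))
  rownames(feats) <- ds$subject_ids
  feats
}

#' Train the base-group classifier
#'
#' A linear-kernel maximum-margin (SVM) binary classifier on the known
#' time-point values and annual change of each marker in the subset,
#' suggesting which class's base gradient a new subject should inherit.
#' Features are assumed pre-normalized, so no internal rescaling is applied.
#'
#' @param train a [longitudinal_dataset()] with both classes.
#' @param markers marker subset (ids or indices; default all).
#' @param cost SVM regularization constant C (default 1).
#' @return an object of class `base_group_svm`.
#' @export
train_base_group_svm <- function(train, markers = NULL, cost = 1) {
  stopifnot(inherits(train, "longitudinal_dataset"))
  if (length(unique(train$labels)) < 2L)
    stop("base-group classifier needs both classes in the training set")
  mi <- resolve_index(markers, train$marker_ids, "marker")
  feats <- base_group_features(train, mi)
  fit <- fit_linear_svm(feats, train$labels, cost = cost)
  structure(list(svm = fit, marker_ids = train$marker_ids[mi],
                 dt = train$dt, cost = cost),
            class = "base_group_svm")
}

#' @export
print.base_group_svm <- function(x, ...) {
  cat("Base-group linear SVM on ", length(x$marker_ids),
      " marker(s) (", 3L * length(x$marker_ids), " features), C = ",
      x$cost, "\n", sep = "")
  invisible(x)
}

#' @export
predict.base_group_svm <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "longitudinal_dataset"))
    base_group_features(newdata, object$marker_ids)
  else as.matrix(newdata)
  if (ncol(feats) != 3L * length(object$marker_ids))
    stop("feature dimension mismatch: expected ",
         3L * length(object$marker_ids), " columns")
  predict_linear_svm(object$svm, feats)$labels
}

# Shared linear-SVM wrapper (e1071/libsvm).  Returns labels in {0,1} and
# decision scores oriented so that larger means more progressor-like.
fit_linear_svm <- function(features, labels, cost = 1) {
  y <- factor(labels, levels = c(0L, 1L))
  if (any(table(y) == 0L)) stop("single-class training set")
  model <- e1071::svm(x = features, y = y, kernel = "linear", cost = cost,
                      scale = FALSE, type = "C-classification")
  # libsvm's decision value is positive for the first class seen in training;
  # record the orientation so scores can be flipped to "larger = class 1".
  pred <- stats::predict(model, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  list(model = model, flip = !identical(first, "1"))
}

predict_linear_svm <- function(fit, features) {
  pred <- stats::predict(fit$model, features, decision.values = TRUE)
  scores <- as.numeric(attr(pred, "decision.values"))
  if (fit$flip) scores <- -scores
  list(labels = as.integer(as.character(pred)), scores = scores)
}

#' Base gradient assignment for a test subject
#'
#' The classifier suggests the base group; the subject's base-gradient
#' vector `alpha` is the corresponding row of the class base-gradient table.
#'
#' @param subject_features one row of [base_group_features()] (or anything
#'   the classifier accepts).
#' @param classifier a [train_base_group_svm()] result, or a function
#'   mapping features to a label in `{0, 1}`.
#' @param base_gradients a `2 x N` table from [compute_base_gradients()].
#' @return list with `class` (0 or 1) and `alpha` (length-N vector).
#' @export
assign_base_gradient <- function(subject_features, classifier, base_gradients) {
  if (inherits(classifier, "base_group_svm") &&
      !identical(classifier$marker_ids, colnames(base_gradients)))
    stop("marker mismatch between classifier and base-gradient table")
  cls <- if (is.function(classifier)) classifier(subject_features)
         else predict(classifier, rbind(subject_features))
  cls <- as.integer(cls)
  if (!cls %in% c(0L, 1L)) stop("classifier must return a label in {0, 1}")
  list(class = cls, alpha = base_gradients[as.character(cls), ])
}

#' Gradient offset of a test subject
#'
#' `OS[m] = alpha[m] - (y(t+dt)[m] - y(t)[m]) / dt`: the assigned base
#' gradient minus the subject's observed first-interval gradient.
#'
#' @param y_t,y_tdt marker-value vectors at the two known visits.
#' @param alpha assigned base-gradient vector.
#' @param dt visit spacing in years (> 0).
#' @return the offset vector.
#' @export
compute_test_offsets <- function(y_t, y_tdt, alpha, dt) {
  if (length(y_t) != length(y_tdt) || length(y_t) != length(alpha))
    stop("`y_t`, `y_tdt` and `alpha` must be conformable")
  if (!all(is.finite(y_t)) || !all(is.finite(y_tdt)) || !all(is.finite(alpha)))
    stop("non-finite inputs")
  alpha - compute_subject_gradient(y_t, y_tdt, dt)
}

#' Weighted multimarker offset
#'
#' Applies the linear-prediction weights to an offset vector:
#' `beta[m] = sum_k mu[k, m] * OS[k]`, i.e. `t(mu) %*% OS`.
#'
#' @param mu `N x N` weight matrix (column `m` predicts marker `m`).
#' @param os length-N offset vector.
#' @return length-N weighted offset vector.
#' @export
weighted_offset <- function(mu, os) {
  mu <- as.matrix(mu)
  if (nrow(mu) != ncol(mu)) stop("`mu` must be square")
  if (length(os) != nrow(mu)) stop("offset vector length must match `mu`")
  drop(crossprod(mu, os))
}

#' One-step forecast of a marker value
#'
#' `y(t+2dt) = y(t+dt) + (alpha + beta) * dt`: linear extrapolation with the
#' base gradient adjusted by the weighted offset correction.
#'
#' @param y_tdt last observed value.
#' @param alpha base gradient (units/yr).
#' @param beta weighted offset correction (units/yr).
#' @param dt visit spacing in years (> 0).
#' @return the forecast value (vectorized).
#' @export
forecast_value <- function(y_tdt, alpha, beta, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  y_tdt + (alpha + beta) * dt
}

#' Forecast third-visit values for a test cohort
#'
#' Per test subject: the base-group classifier suggests the class, whose
#' base-gradient row becomes `alpha`; the subject's gradient offsets
#' `OS = alpha - observed gradient` are propagated through the weight matrix
#' to a predicted future offset `t(mu) %*% OS`; since offsets are defined as
#' base-minus-gradient, the forecast second-interval gradient is
#' `alpha - t(mu) %*% OS`, stored as `alpha + beta` with
#' `beta = -t(mu) %*% OS` so that `predicted = y(t+dt) + (alpha + beta)*dt`
#' holds cell by cell.  Observed third visits, when present, are carried
#' along for error assessment.
#'
#' @param test a [longitudinal_dataset()] with at least the first two visits.
#' @param model a fitted [fit_weights_loo()] model.
#' @param classifier a [train_base_group_svm()] result, a function mapping
#'   feature rows to labels, or `"oracle"` to use the test subjects' true
#'   labels as the base group.
#' @return an object of class `forecast_set`.
#' @export
forecast_dataset <- function(test, model, classifier) {
  stopifnot(inherits(test, "longitudinal_dataset"),
            inherits(model, "gradient_model"))
  mi <- resolve_index(model$marker_ids, test$marker_ids, "marker")
  n <- n_subjects(test)
  N <- length(mi)
  feats <- base_group_features(test, mi)

  base_class <- integer(n)
  if (identical(classifier, "oracle")) {
    base_class <- test$labels
  } else if (inherits(classifier, "base_group_svm")) {
    if (!identical(classifier$marker_ids, model$marker_ids))
      stop("marker mismatch between classifier and model")
    base_class <- predict(classifier, feats)
  } else if (is.function(classifier)) {
    base_class <- vapply(seq_len(n),
                         function(i) as.integer(classifier(feats[i, ])),
                         integer(1))
  } else stop("unsupported `classifier`")
  if (!all(base_class %in% c(0L, 1L)))
    stop("base-group labels must be in {0, 1}")

  y1 <- matrix(test$values[, mi, 1], n, N)
  y2 <- matrix(test$values[, mi, 2], n, N)
  alpha <- model$base_gradients[as.character(base_class), , drop = FALSE]
  os <- alpha - (y2 - y1) / test$dt
  beta <- -os %*% model$mu             # rows: -t(mu) %*% OS_i
  predicted <- y2 + (alpha + beta) * test$dt
  observed <- matrix(test$values[, mi, 3], n, N)

  dn <- list(test$subject_ids, model$marker_ids)
  dimnames(predicted) <- dimnames(observed) <- dimnames(alpha) <-
    dimnames(beta) <- dn
  structure(
    list(subject_ids = test$subject_ids, marker_ids = model$marker_ids,
         labels = test$labels, predicted = predicted, observed = observed,
         base_class = stats::setNames(base_class, test$subject_ids),
         alpha = alpha, beta = beta, y_tdt = y2, dt = test$dt),
    class = "forecast_set")
}

#' @rdname forecast_dataset
#' @param object a `gradient_model`.
#' @param newdata the test [longitudinal_dataset()].
#' @param ... ignored.
#' @export
predict.gradient_model <- function(object, newdata,
                                   classifier = "oracle", ...) {
  forecast_dataset(newdata, object, classifier)
}

#' @export
print.forecast_set <- function(x, ...) {
  cat("Forecast set: ", length(x$subject_ids), " subjects x ",
      length(x$marker_ids), " markers\n", sep = "")
  err <- mae(x)
  if (is.finite(err))
    cat("  MAE vs observed third visits: ", signif(err, 4), "\n", sep = "")
  invisible(x)
}

#' @export
residuals.forecast_set <- function(object, ...) {
  object$predicted - object$observed
}

#' Mean absolute forecast error
#'
#' @param fs a [forecast_dataset()] result.
#' @param percent report on the 0-100 scale (for normalized data)?
#' @return mean of `|predicted - observed|` over all cells with an observed
#'   value (`NA` if none).
#' @export
mae <- function(fs, percent = FALSE) {
  stopifnot(inherits(fs, "forecast_set"))
  err <- abs(fs$predicted - fs$observed)
  if (all(is.na(err))) return(NA_real_)
  m <- mean(err, na.rm = TRUE)
  if (percent) 100 * m else m
}

#' @export
as.data.frame.forecast_set <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  n <- length(x$subject_ids)
  N <- length(x$marker_ids)
  data.frame(
    subject_id = rep(x$subject_ids, times = N),
    marker_id = rep(x$marker_ids, each = n),
    predicted = as.vector(x$predicted),
    observed = as.vector(x$observed),
    abs_error = as.vector(abs(x$predicted - x$observed)),
    base_class = rep(unname(x$base_class), times = N),
    stringsAsFactors = FALSE)
}
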