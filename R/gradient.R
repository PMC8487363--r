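#' Piecewise gradient between two consecutive readings
#'
#' @param x_t,x_tdt readings at consecutive visits (vectorized).
#' @param dt visit spacing in years (> 0).
#' @return `(x_tdt - x_t) / dt`, in units per year.
#' @export
compute_subject_gradient <- function(x_t, x_tdt, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  (x_tdt - x_t) / dt
}

#' Class-average base gradients
#'
#' The base gradient of marker `m` for class `c` is the first-interval
#' piecewise gradient `(x(t+dt) - x(t)) / dt` averaged over the class-`c`
#' subjects of the training set: the typical annual change of that marker in
#' that class.
#'
#' @param train a [longitudinal_dataset()] with both classes present.
#' @param markers marker subset (ids or indices; default all).
#' @return a `2 x N` matrix, rows `"0"` (stable) and `"1"` (progressor),
#'   columns the selected markers.
#' @export
compute_base_gradients <- function(train, markers = NULL) {
  stopifnot(inherits(train, "longitudinal_dataset"))
  mi <- resolve_index(markers, train$marker_ids, "marker")
  grads <- (train$values[, mi, 2, drop = FALSE] -
            train$values[, mi, 1, drop = FALSE]) / train$dt
  grads <- matrix(grads, n_subjects(train), length(mi))
  out <- matrix(NA_real_, 2L, length(mi),
                dimnames = list(c("0", "1"), train$marker_ids[mi]))
  for (lab in c(0L, 1L)) {
    rows <- which(train$labels == lab)
    if (!length(rows))
      stop("class ", lab, " absent: base gradients need >= 1 subject per class")
    out[as.character(lab), ] <- colMeans(grads[rows, , drop = FALSE])
  }
  out
}

#' Gradient-offset system of a training set
#'
#' For each training subject `i` with true class `c`, the offset of marker
#' `m` is the class base gradient minus the subject's observed gradient:
#' `A[i, m] = delta_m^c - (x(t+dt) - x(t))/dt` on the first interval and
#' `B[i, m] = delta_m^c - (x(t+2dt) - x(t+dt))/dt` on the second (the future
#' offset).  The linear-prediction weights solve `A %*% mu[, m] = B[, m]`.
#'
#' @param train a complete [longitudinal_dataset()] (third visits observed).
#' @param base a base-gradient table from [compute_base_gradients()]
#'   covering all requested markers.
#' @param markers marker subset (default: the columns of `base`).
#' @return an object of class `offset_system`: list with matrices `A`, `B`
#'   and the subject/marker ids.
#' @export
build_offset_system <- function(train, base, markers = NULL) {
  stopifnot(inherits(train, "longitudinal_dataset"))
  if (is.null(markers)) markers <- colnames(base)
  mi <- resolve_index(markers, train$marker_ids, "marker")
  ids <- train$marker_ids[mi]
  if (!all(ids %in% colnames(base)))
    stop("`base` does not cover marker(s): ",
         paste(setdiff(ids, colnames(base)), collapse = ", "))
  third <- train$values[, mi, 3, drop = FALSE]
  if (anyNA(third))
    stop("training requires full trajectories: subject(s) lacking a third ",
         "visit: ",
         paste(train$subject_ids[apply(is.na(third), 1, any)], collapse = ", "))
  n <- n_subjects(train)
  g1 <- matrix((train$values[, mi, 2] - train$values[, mi, 1]) / train$dt,
               n, length(mi))
  g2 <- matrix((train$values[, mi, 3] - train$values[, mi, 2]) / train$dt,
               n, length(mi))
  base_rows <- base[as.character(train$labels), ids, drop = FALSE]
  A <- base_rows - g1
  B <- base_rows - g2
  dimnames(A) <- dimnames(B) <- list(train$subject_ids, ids)
  structure(list(A = A, B = B, subject_ids = train$subject_ids,
                 marker_ids = ids),
            class = "offset_system")
}

#' Least-squares linear-prediction weights
#'
#' Solves `A %*% mu[, m] = B[, m]` for every marker `m` in the least-squares
#' sense.  When `t(A) %*% A` is invertible the solution equals the normal
#' equations form `(A'A)^{-1} A' B_m`; otherwise (more markers than
#' subjects, or collinear offsets) the minimum-norm solution is returned via
#' the singular value decomposition, with a warning.
#'
#' @param sys an [build_offset_system()] result, or a list with matrices
#'   `A` (n x N) and `B` (n x N).
#' @param tol singular values below `tol` are treated as zero; default
#'   `max(dim(A)) * .Machine$double.eps * max(singular value)`.
#' @return the `N x N` weight matrix `mu`; column `m` predicts marker `m`'s
#'   future offset from all current offsets.
#' @export
solve_weights <- function(sys, tol = NULL) {
  A <- as.matrix(sys$A)
  B <- as.matrix(sys$B)
  if (!nrow(A)) stop("empty offset system")
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B))
    stop("`A` and `B` must share shape")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("non-finite entries in the offset system")
  N <- ncol(A)
  sv <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r < N)
    warning("rank-deficient offset system (rank ", r, " < ", N,
            "): returning the minimum-norm solution")
  if (r == 0L) {
    mu <- matrix(0, N, N)
  } else {
    U <- sv$u[, seq_len(r), drop = FALSE]
    V <- sv$v[, seq_len(r), drop = FALSE]
    mu <- V %*% ((crossprod(U, B)) / sv$d[seq_len(r)])
  }
  dimnames(mu) <- list(colnames(A), colnames(A))
  mu
}

#' Fit the gradient-offset model with leave-one-out weight averaging
#'
#' Fits the full longitudinal-trajectory model on a training set: base
#' gradients per class on the complete training set, and the
#' linear-prediction weight matrix `mu` obtained by solving the
#' gradient-offset system on each leave-one-out fold (all retained training
#' subjects) and averaging the per-fold solutions element-wise.
#'
#' By default the base gradients are held fixed at their full-training-set
#' values throughout the LOO loop, so each fold differs only in the rows of
#' the offset system; `recompute_base = TRUE` re-estimates them on the
#' retained subjects of every fold (folds that lose a class entirely are
#' then skipped with a warning).
#'
#' @param train a complete [longitudinal_dataset()] with >= 3 subjects.
#' @param markers marker subset (ids or indices; default all).
#' @param recompute_base recompute class base gradients inside each fold?
#' @return an object of class `gradient_model`: list with `dt`,
#'   `marker_ids`, `base_gradients` (2 x N), `mu` (N x N) and
#'   `n_loo_folds`.
#' @export
fit_weights_loo <- function(train, markers = NULL, recompute_base = FALSE) {
  stopifnot(inherits(train, "longitudinal_dataset"))
  n <- n_subjects(train)
  if (n < 3L) stop("LOO weight averaging needs at least 3 training subjects")
  mi <- resolve_index(markers, train$marker_ids, "marker")
  base_full <- compute_base_gradients(train, mi)
  N <- length(mi)
  if (anyNA(train$values[, mi, 3]))
    stop("training requires full trajectories (observed third visits)")
  g1 <- matrix((train$values[, mi, 2] - train$values[, mi, 1]) / train$dt,
               n, N)
  g2 <- matrix((train$values[, mi, 3] - train$values[, mi, 2]) / train$dt,
               n, N)
  labels <- train$labels

  mu_sum <- matrix(0, N, N)
  used <- 0L
  skipped <- 0L
  rank_warned <- FALSE
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    if (recompute_base) {
      lab_keep <- labels[keep]
      if (length(unique(lab_keep)) < 2L) { skipped <- skipped + 1L; next }
      base_fold <- rbind(
        "0" = colMeans(g1[keep[lab_keep == 0L], , drop = FALSE]),
        "1" = colMeans(g1[keep[lab_keep == 1L], , drop = FALSE]))
    } else {
      base_fold <- base_full
    }
    base_rows <- base_fold[as.character(labels[keep]), , drop = FALSE]
    sys <- list(A = base_rows - g1[keep, , drop = FALSE],
                B = base_rows - g2[keep, , drop = FALSE])
    mu_fold <- withCallingHandlers(
      solve_weights(sys),
      warning = function(w) {
        if (grepl("rank-deficient", conditionMessage(w))) {
          rank_warned <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    mu_sum <- mu_sum + mu_fold
    used <- used + 1L
  }
  if (skipped > 0L)
    warning(skipped, " LOO fold(s) skipped (a class was absent)")
  if (rank_warned)
    warning("rank-deficient offset system in one or more LOO folds; ",
            "minimum-norm solutions used")
  if (used == 0L) stop("all LOO folds were skipped; cannot fit weights")
  mu <- mu_sum / used
  dimnames(mu) <- list(train$marker_ids[mi], train$marker_ids[mi])
  structure(
    list(dt = train$dt, marker_ids = train$marker_ids[mi],
         base_gradients = base_full, mu = mu, n_loo_folds = used),
    class = "gradient_model")
}

#' @export
print.gradient_model <- function(x, ...) {
  cat("Weighted gradient-offset model\n")
  cat("  markers: ", length(x$marker_ids), " (",
      paste(utils::head(x$marker_ids, 4), collapse = ", "),
      if (length(x$marker_ids) > 4) ", ..." else "", ")\n", sep = "")
  cat("  dt = ", x$dt, " y; weights averaged over ", x$n_loo_folds,
      " LOO folds\n", sep = "")
  invisible(x)
}

#' @export
coef.gradient_model <- function(object, ...) object$mu

#' @export
summary.gradient_model <- function(object, ...) {
  cat("Weighted gradient-offset model (dt = ", object$dt, " y, ",
      object$n_loo_folds, " LOO folds)\n\n", sep = "")
  cat("Base gradients (units/yr):\n")
  print(signif(object$base_gradients, 4))
  cat("\nLinear-prediction weights mu (column m predicts marker m):\n")
  print(signif(object$mu, 4))
  invisible(object)
}

MODEL_SCHEMA_VERSION <- "1"

#' Serialize / load a fitted gradient model
#'
#' Models round-trip through a versioned JSON artifact at full double
#' precision, so `read_model(write_model(m, path))` reproduces `m` exactly.
#'
#' @param model a [fit_weights_loo()] result.
#' @param path file path for the JSON artifact.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   `gradient_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "gradient_model"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    dt = model$dt,
    marker_ids = model$marker_ids,
    base_gradients = list(stable = unname(model$base_gradients["0", ]),
                          progressor = unname(model$base_gradients["1", ])),
    mu = unname(lapply(seq_len(nrow(model$mu)),
                       function(i) model$mu[i, ])),
    n_loo_folds = model$n_loo_folds)
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  for (field in c("schema_version", "dt", "marker_ids", "base_gradients",
                  "mu", "n_loo_folds")) {
    if (is.null(obj[[field]])) stop("model artifact missing field: ", field)
  }
  if (!identical(as.character(obj$schema_version), MODEL_SCHEMA_VERSION))
    stop("model schema version mismatch: got ", obj$schema_version,
         ", expected ", MODEL_SCHEMA_VERSION)
  ids <- as.character(obj$marker_ids)
  N <- length(ids)
  mu <- obj$mu
  if (is.list(mu)) mu <- do.call(rbind, mu)
  mu <- as.matrix(mu)
  if (!identical(dim(mu), c(N, N)))
    stop("model artifact `mu` has shape ", paste(dim(mu), collapse = " x "),
         ", expected ", N, " x ", N)
  bg <- rbind("0" = as.numeric(obj$base_gradients$stable),
              "1" = as.numeric(obj$base_gradients$progressor))
  if (ncol(bg) != N) stop("model artifact `base_gradients` shape mismatch")
  colnames(bg) <- ids
  dimnames(mu) <- list(ids, ids)
  structure(list(dt = as.numeric(obj$dt), marker_ids = ids,
                 base_gradients = bg, mu = mu,
                 n_loo_folds = as.integer(obj$n_loo_folds)),
            class = "gradient_model")
}
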