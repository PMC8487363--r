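#' Normalize marker trajectories by per-marker maximum
#'
#' Divides every reading of a marker by that marker's maximum absolute value
#' over all subjects and all visits, so positive-valued markers land on
#' `(0, 1]` while within-subject longitudinal shape is preserved up to a
#' common scale factor.  The operation is idempotent and equivariant to
#' positive rescaling of a marker.
#'
#' By default the scale factors come from the dataset itself, i.e. the whole
#' cohort before any train-test split; pass `scale` (e.g. factors computed
#' from a training fold via [marker_scales()]) for leakage-free
#' normalization of held-out data.
#'
#' @param ds a [longitudinal_dataset()].
#' @param scale optional named per-marker scale factors to apply instead of
#'   the dataset's own maxima.
#' @return the normalized dataset, with the applied factors in
#'   `attr(, "marker_scales")`.
#' @export
normalize_dataset <- function(ds, scale = NULL) {
  stopifnot(inherits(ds, "longitudinal_dataset"))
  if (is.null(scale)) scale <- marker_scales(ds)
  if (length(scale) != length(ds$marker_ids))
    stop("`scale` must supply one factor per marker")
  if (!is.null(names(scale))) {
    pos <- match(ds$marker_ids, names(scale))
    if (anyNA(pos)) stop("`scale` is missing marker(s): ",
                         paste(ds$marker_ids[is.na(pos)], collapse = ", "))
    scale <- scale[pos]
  }
  if (any(!is.finite(scale) | scale <= 0))
    stop("scale factors must be positive and finite")
  vals <- sweep(ds$values, 2, scale, "/")
  out <- longitudinal_dataset(vals, labels = ds$labels, dt = ds$dt,
                              subject_ids = ds$subject_ids,
                              marker_ids = ds$marker_ids,
                              require_complete = !anyNA(ds$values))
  attr(out, "marker_scales") <- stats::setNames(as.numeric(scale),
                                                ds$marker_ids)
  out
}

#' @rdname normalize_dataset
#' @export
marker_scales <- function(ds) {
  stopifnot(inherits(ds, "longitudinal_dataset"))
  s <- apply(abs(ds$values), 2, max, na.rm = TRUE)
  zero <- ds$marker_ids[s == 0]
  if (length(zero))
    stop("degenerate marker(s) with all-zero readings: ",
         paste(zero, collapse = ", "))
  stats::setNames(s, ds$marker_ids)
}

#' Two-sample pooled-variance Student's t-test
#'
#' Classic equal-variance two-sample t statistic with
#' `df = n1 + n2 - 2` and a two-sided p-value.  Degenerate inputs follow the
#' conventions used by the marker-ranking step: zero pooled variance with
#' equal means gives `t = 0, p = 1`; zero pooled variance with unequal means
#' gives `t = +/-Inf, p = 0` (both with a warning).
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return a list with `statistic`, `df` and `p.value`.
#' @export
pooled_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite readings")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    warning("degenerate marker: zero pooled variance")
    if (delta == 0) return(list(statistic = 0, df = df, p.value = 1))
    return(list(statistic = sign(delta) * Inf, df = df, p.value = 0))
  }
  tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df))
}

#' Rank markers by baseline discriminative significance
#'
#' Runs a two-sample t-test (pooled-variance Student by default, Welch
#' optionally) on the baseline (first-visit) readings of each marker,
#' progressors vs stables, and orders markers by ascending p-value.  Ties
#' keep the original marker order (stable sort).  The ranking induces the
#' nested incremental subsets used by the model-selection loop: subset `k`
#' is the top-`k` ranked markers.
#'
#' @param ds a [longitudinal_dataset()] with both classes present.
#' @param method `"student"` (pooled variance, default) or `"welch"`.
#' @return an object of class `ranked_markers`: list with `table` (a
#'   data.frame of `marker_id`, `t_statistic`, `p_value`, `rank` in original
#'   marker order), `order` (marker ids by ascending p) and `subsets`.
#' @export
rank_markers <- function(ds, method = c("student", "welch")) {
  stopifnot(inherits(ds, "longitudinal_dataset"))
  method <- match.arg(method)
  baseline <- matrix(ds$values[, , 1], n_subjects(ds),
                     length(ds$marker_ids))
  pos <- ds$labels == 1L
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("both classes need at least 2 subjects for ranking")
  res <- lapply(seq_len(ncol(baseline)), function(m) {
    x <- baseline[pos, m]; y <- baseline[!pos, m]
    if (method == "student") pooled_t_test(x, y)
    else { tt <- stats::t.test(x, y); list(statistic = unname(tt$statistic),
                                           df = unname(tt$parameter),
                                           p.value = tt$p.value) }
  })
  p <- vapply(res, `[[`, numeric(1), "p.value")
  tstat <- vapply(res, `[[`, numeric(1), "statistic")
  ord <- order(p)  # stable: ties keep original marker order
  tab <- data.frame(marker_id = ds$marker_ids,
                    t_statistic = tstat, p_value = p,
                    rank = match(seq_along(p), ord),
                    stringsAsFactors = FALSE)
  ordered_ids <- ds$marker_ids[ord]
  structure(
    list(table = tab, order = ordered_ids,
         subsets = lapply(seq_along(ordered_ids),
                          function(k) ordered_ids[seq_len(k)]),
         method = method),
    class = "ranked_markers")
}

#' @export
print.ranked_markers <- function(x, n = 5, ...) {
  cat("Marker ranking (", x$method, " t-test on baseline readings)\n",
      sep = "")
  top <- x$table[order(x$table$rank), ]
  print(utils::head(top, n), row.names = FALSE)
  if (nrow(top) > n) cat("... and", nrow(top) - n, "more markers\n")
  invisible(x)
}

#' Incremental marker subsets from a ranking
#'
#' @param rm a [rank_markers()] result.
#' @param max_size largest subset size (1 <= max_size <= number of markers).
#' @return list of character vectors; element `k` holds the top-`k` markers.
#' @export
build_subsets <- function(rm, max_size) {
  stopifnot(inherits(rm, "ranked_markers"))
  nm <- length(rm$order)
  if (!is.numeric(max_size) || length(max_size) != 1L ||
      max_size != round(max_size) || max_size < 1L || max_size > nm)
    stop("`max_size` must be an integer in [1, ", nm, "]")
  rm$subsets[seq_len(max_size)]
}
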