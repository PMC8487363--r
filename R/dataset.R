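#' Longitudinal biomarker dataset
#'
#' Container for a cohort of subjects observed on a panel of markers at three
#' equally spaced visits (`t`, `t + dt`, `t + 2*dt`).  Readings are stored as a
#' `subjects x markers x 3` array; each subject carries a binary class label
#' (1 = progressor, 0 = stable).  Test cohorts used only for forecasting may
#' carry `NA` in the third visit slot (set `require_complete = FALSE`).
#'
#' @param values numeric array of dimension `n_subjects x n_markers x 3`
#'   holding readings at visits 1..3.
#' @param labels integer vector of 0/1 class labels, one per subject
#'   (1 = progressor, 0 = stable).  Both classes must be present.
#' @param dt follow-up spacing in years (> 0).
#' @param subject_ids,marker_ids optional identifier vectors; defaults are
#'   generated.
#' @param require_complete if `TRUE` (default) every reading must be finite;
#'   if `FALSE` a subject's third visit may be entirely `NA` (forecast-only
#'   input), but the first two visits must always be finite.
#'
#' @return An object of class `longitudinal_dataset`: a list with elements
#'   `values`, `labels`, `dt`, `subject_ids`, `marker_ids`.
#' @export
longitudinal_dataset <- function(values, labels, dt,
                                 subject_ids = NULL, marker_ids = NULL,
                                 require_complete = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-dimensional array (subjects x markers x visits)")
  if (dim(values)[3] != 3L)
    stop("`values` must have exactly 3 visit slots per subject per marker")
  n <- dim(values)[1]
  nm <- dim(values)[2]
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (years)")
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("`labels` must have one entry per subject")
  if (!all(labels %in% c(0L, 1L)))
    stop("`labels` must be 0 (stable) or 1 (progressor)")
  if (length(unique(labels)) < 2L)
    stop("both classes (0 and 1) must be present in `labels`")
  if (is.null(subject_ids)) subject_ids <- sprintf("subj%03d", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- sprintf("marker%02d", seq_len(nm))
  subject_ids <- as.character(subject_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids")
  if (length(subject_ids) != n || length(marker_ids) != nm)
    stop("identifier length does not match `values` dimensions")

  first_two <- values[, , 1:2, drop = FALSE]
  if (!all(is.finite(first_two)))
    stop("readings at the first two visits must all be finite")
  third <- values[, , 3, drop = FALSE]
  if (require_complete) {
    if (!all(is.finite(third)))
      stop("all readings must be finite (subjects with missing follow-ups ",
           "are not admitted; use `require_complete = FALSE` for ",
           "forecast-only input)")
  } else {
    # third visit must be all-observed or all-missing per subject
    for (i in seq_len(n)) {
      row <- third[i, , 1]
      if (anyNA(row) && !all(is.na(row)))
        stop("subject ", subject_ids[i],
             ": third visit must be fully observed or fully missing")
      if (!anyNA(row) && !all(is.finite(row)))
        stop("subject ", subject_ids[i], ": non-finite third-visit reading")
    }
  }

  dimnames(values) <- list(subject_ids, marker_ids, c("t0", "t1", "t2"))
  structure(
    list(values = values, labels = labels, dt = dt,
         subject_ids = subject_ids, marker_ids = marker_ids),
    class = "longitudinal_dataset")
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  cat("Longitudinal dataset: ", length(x$subject_ids), " subjects (",
      sum(x$labels == 1L), " progressor / ", sum(x$labels == 0L),
      " stable), ", length(x$marker_ids), " markers, 3 visits, dt = ",
      x$dt, " y\n", sep = "")
  invisible(x)
}

#' @export
dim.longitudinal_dataset <- function(x) dim(x$values)

n_subjects <- function(ds) dim(ds$values)[1]

#' Subset a longitudinal dataset by subject and/or marker
#'
#' @param ds a [longitudinal_dataset()].
#' @param subjects subject indices, logical mask, or ids (default: all).
#' @param markers marker indices, logical mask, or ids (default: all).
#' @param require_complete passed through to the constructor.
#' @return a `longitudinal_dataset` restricted to the selection.
#' @export
subset_dataset <- function(ds, subjects = NULL, markers = NULL,
                           require_complete = TRUE) {
  stopifnot(inherits(ds, "longitudinal_dataset"))
  si <- resolve_index(subjects, ds$subject_ids, "subject")
  mi <- resolve_index(markers, ds$marker_ids, "marker")
  longitudinal_dataset(ds$values[si, mi, , drop = FALSE],
                       labels = ds$labels[si], dt = ds$dt,
                       subject_ids = ds$subject_ids[si],
                       marker_ids = ds$marker_ids[mi],
                       require_complete = require_complete)
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ", what, " id(s): ",
                         paste(idx[is.na(pos)], collapse = ", "))
    return(pos)
  }
  if (is.logical(idx)) {
    if (length(idx) != length(ids)) stop(what, " mask length mismatch")
    return(which(idx))
  }
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > length(ids))) stop(what, " index out of range")
  idx
}

#' Convert a longitudinal dataset to/from tidy long format
#'
#' The long format has one row per reading with columns `subject_id`, `label`,
#' `marker_id`, `visit_time` (years from baseline) and `value`.
#'
#' @param x a [longitudinal_dataset()].
#' @param row.names,optional,... ignored (S3 signature).
#' @return a `data.frame` in long format.
#' @export
as.data.frame.longitudinal_dataset <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  n <- length(x$subject_ids)
  nm <- length(x$marker_ids)
  df <- data.frame(
    subject_id = rep(x$subject_ids, times = nm * 3L),
    label = rep(x$labels, times = nm * 3L),
    marker_id = rep(rep(x$marker_ids, each = n), times = 3L),
    visit_time = rep((0:2) * x$dt, each = n * nm),
    value = as.vector(x$values),
    stringsAsFactors = FALSE)
  df <- df[order(df$subject_id, df$marker_id, df$visit_time), ]
  rownames(df) <- NULL
  df
}

#' Write a longitudinal dataset as a long-format CSV
#'
#' @param ds a [longitudinal_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ds, path) {
  df <- as.data.frame(ds)
  df <- df[!is.na(df$value), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a longitudinal dataset from a long-format CSV
#'
#' Expects columns `subject_id`, `label`, `marker_id`, `visit_time`, `value`.
#' Each subject must carry a single consistent label and, per marker, visits at
#' `{t0, t0 + dt, t0 + 2 dt}` for a dataset-wide `dt` (subjects providing only
#' the first two visits are admitted when `require_complete = FALSE`).
#' Subjects violating the visit-structure rule are dropped with a message
#' listing them, mirroring cohort-inclusion rules that ignore subjects with
#' missing values at designated follow-up times.
#'
#' @param path CSV file path.
#' @param require_complete if `TRUE` (default) subjects need all three visits.
#' @param dt optional follow-up spacing; inferred from the data if `NULL`.
#' @return a [longitudinal_dataset()].
#' @export
read_long_csv <- function(path, require_complete = TRUE, dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "label", "marker_id", "visit_time", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$value) | is.na(df$visit_time))
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  # consistent label per subject
  lab_tab <- tapply(df$label, df$subject_id, function(l) length(unique(l)))
  incons <- names(lab_tab)[lab_tab > 1L]
  if (length(incons))
    stop("inconsistent label for subject(s): ", paste(incons, collapse = ", "))

  key <- paste(df$subject_id, df$marker_id, df$visit_time)
  if (anyDuplicated(key))
    stop("duplicate (subject, marker, visit_time) row(s), first at line ",
         which(duplicated(key))[1] + 1L)

  subjects <- unique(df$subject_id)
  markers <- sort(unique(df$marker_id))
  # infer dt from visit spacings if not supplied
  if (is.null(dt)) {
    spacings <- unlist(lapply(split(df$visit_time, df$subject_id), function(v) {
      u <- sort(unique(v)); if (length(u) >= 2) diff(u) else numeric(0)
    }))
    if (!length(spacings)) stop("cannot infer dt: no repeated visits")
    dt <- min(spacings)
  }

  ok <- logical(length(subjects))
  diag_msgs <- character(0)
  arr <- array(NA_real_, dim = c(length(subjects), length(markers), 3L))
  labels <- integer(length(subjects))
  for (i in seq_along(subjects)) {
    sub <- df[df$subject_id == subjects[i], ]
    labels[i] <- sub$label[1]
    valid <- TRUE
    times <- sort(unique(sub$visit_time))
    want_n <- if (require_complete) 3L else c(2L, 3L)
    if (!(length(times) %in% want_n)) {
      valid <- FALSE
      diag_msgs <- c(diag_msgs, paste0(subjects[i], ": ", length(times),
                                       " visit time(s)"))
    } else if (max(abs(diff(times) - dt)) > 1e-8 * max(dt, 1)) {
      valid <- FALSE
      diag_msgs <- c(diag_msgs, paste0(subjects[i],
                                       ": visits not spaced by dt = ", dt))
    } else {
      for (k in seq_along(times)) {
        rows <- sub[abs(sub$visit_time - times[k]) < 1e-9 * max(dt, 1), ]
        pos <- match(markers, rows$marker_id)
        if (anyNA(pos)) {
          valid <- FALSE
          diag_msgs <- c(diag_msgs, paste0(subjects[i],
                                           ": incomplete marker panel at t = ",
                                           times[k]))
          break
        }
        arr[i, , k] <- rows$value[pos]
      }
    }
    ok[i] <- valid
  }
  if (!all(ok)) {
    message("rejected ", sum(!ok), " subject(s):\n  ",
            paste(diag_msgs, collapse = "\n  "))
  }
  if (!any(ok)) stop("no subject satisfies the visit-structure rule")
  longitudinal_dataset(arr[ok, , , drop = FALSE], labels = labels[ok], dt = dt,
                       subject_ids = subjects[ok], marker_ids = markers,
                       require_complete = require_complete)
}
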