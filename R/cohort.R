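#' Specification of a synthetic longitudinal cohort
#'
#' Defines the generative model for a two-class cohort (progressors vs
#' stables) observed on `n_markers` positive-scaled markers at three equally
#' spaced visits.  Each subject draws a baseline uniformly per marker, a
#' subject-specific first-interval slope around its class rate, and a
#' second-interval slope whose deviation from the class rate is a linear
#' combination (through `coupling_matrix`) of the realized first-interval
#' deviations of *all* markers.  Measurement noise is added to the observed
#' readings, not the latent slopes, so the latent trajectory stays
#' piecewise-linear.
#'
#' The coupling matrix follows the linear-prediction-weight convention:
#' column `m` holds the weights mapping every marker's first-interval
#' gradient deviation to marker `m`'s second-interval deviation, so the
#' matrix is exactly the weight matrix a gradient-offset regression should
#' recover (see [solve_weights()]).
#'
#' Defaults emulate a mild-cognitive-impairment study cohort: 49 progressors
#' and 70 stables at 6-month spacing, markers on heterogeneous positive
#' scales (log-spaced 1 to 100, standing in for cognitive scores vs regional
#' brain volumes), stable decline of 2 %/yr of scale vs progressor decline of
#' 8 %/yr, between-subject slope spread of 2 % and measurement noise of 1 %
#' of scale, and no cross-marker coupling.
#'
#' @param n_progressor,n_stable subject counts per class (each >= 2).
#' @param n_markers number of markers.
#' @param dt visit spacing in years (> 0).
#' @param slope_progressor,slope_stable per-marker latent rates (units/yr);
#'   scalars are recycled.
#' @param coupling_matrix `n_markers x n_markers` dimensionless weights (the
#'   ground-truth linear-prediction matrix); default zero.
#' @param subject_slope_sd sd of per-subject slope around the class rate
#'   (units/yr); scalar or per-marker.
#' @param noise_sd sd of additive measurement noise on readings (units);
#'   scalar or per-marker.
#' @param baseline_ranges `n_markers x 2` matrix of (min, max) uniform
#'   baseline ranges, min < max.
#' @param center_slopes if `TRUE` (default) subject slopes are re-centred
#'   within class so the empirical class-mean rate equals the nominal rate
#'   exactly; nominal parameters are then exact finite-sample class means,
#'   which makes parameter-recovery checks sharp.
#' @param seed integer RNG seed; identical specs generate bit-identical
#'   cohorts.
#'
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [true_offsets()]
#' @export
cohort_spec <- function(n_progressor = 49, n_stable = 70, n_markers = 10,
                        dt = 0.5,
                        slope_progressor = NULL, slope_stable = NULL,
                        coupling_matrix = NULL,
                        subject_slope_sd = NULL, noise_sd = NULL,
                        baseline_ranges = NULL,
                        center_slopes = TRUE, seed = 1L) {
  chk_count <- function(x, nm, min) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x != round(x) || x < min)
      stop("invalid `", nm, "`: must be an integer >= ", min)
    as.integer(x)
  }
  n_progressor <- chk_count(n_progressor, "n_progressor", 2)
  n_stable <- chk_count(n_stable, "n_stable", 2)
  n_markers <- chk_count(n_markers, "n_markers", 1)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("invalid `dt`: must be a single positive number")
  seed <- chk_count(seed, "seed", 0)

  scales <- if (n_markers == 1L) 1 else 10^seq(0, 2, length.out = n_markers)
  per_marker <- function(x, nm, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1L) x <- rep(x, n_markers)
    if (length(x) != n_markers || !all(is.finite(x)))
      stop("invalid `", nm, "`: need ", n_markers, " finite value(s)")
    as.numeric(x)
  }
  slope_progressor <- per_marker(slope_progressor, "slope_progressor",
                                 -0.08 * scales)
  slope_stable <- per_marker(slope_stable, "slope_stable", -0.02 * scales)
  subject_slope_sd <- per_marker(subject_slope_sd, "subject_slope_sd",
                                 0.02 * scales)
  noise_sd <- per_marker(noise_sd, "noise_sd", 0.01 * scales)
  if (any(subject_slope_sd < 0)) stop("invalid `subject_slope_sd`: must be >= 0")
  if (any(noise_sd < 0)) stop("invalid `noise_sd`: must be >= 0")

  if (is.null(coupling_matrix))
    coupling_matrix <- matrix(0, n_markers, n_markers)
  coupling_matrix <- as.matrix(coupling_matrix)
  if (!is.numeric(coupling_matrix) ||
      !identical(dim(coupling_matrix), c(n_markers, n_markers)) ||
      !all(is.finite(coupling_matrix)))
    stop("invalid `coupling_matrix`: must be a finite ", n_markers, " x ",
         n_markers, " matrix")

  if (is.null(baseline_ranges))
    baseline_ranges <- cbind(0.5 * scales, 1.0 * scales)
  baseline_ranges <- as.matrix(baseline_ranges)
  if (!identical(dim(baseline_ranges), c(n_markers, 2L)) &&
      !identical(dim(baseline_ranges), c(n_markers, 2)))
    stop("invalid `baseline_ranges`: must be an ", n_markers, " x 2 matrix")
  if (!all(is.finite(baseline_ranges)) ||
      any(baseline_ranges[, 1] >= baseline_ranges[, 2]))
    stop("invalid `baseline_ranges`: need min < max per marker")

  structure(
    list(n_progressor = n_progressor, n_stable = n_stable,
         n_markers = n_markers, dt = dt,
         slope_progressor = slope_progressor, slope_stable = slope_stable,
         coupling_matrix = coupling_matrix,
         subject_slope_sd = subject_slope_sd, noise_sd = noise_sd,
         baseline_ranges = baseline_ranges,
         center_slopes = isTRUE(center_slopes), seed = seed),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec: ", x$n_progressor, " progressors + ",
      x$n_stable, " stables, ", x$n_markers, " markers, dt = ", x$dt,
      " y, seed = ", x$seed, "\n", sep = "")
  cat("  coupling: ",
      if (all(x$coupling_matrix == 0)) "none" else "non-zero", "; noise sd ",
      signif(min(x$noise_sd), 3), "..", signif(max(x$noise_sd), 3),
      "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort from the generative model described in [cohort_spec()].
#' For subject `i` of class `c` and marker `m`:
#' `x(t) ~ U(range_m)`, slope `g ~ N(slope_c[m], subject_slope_sd[m]^2)`,
#' `x(t+dt) = x(t) + g*dt + e1`; the realized first-interval deviation is
#' `d[m] = slope_c[m] - (x(t+dt) - x(t))/dt`, the second-interval slope is
#' `g2[m] = slope_c[m] - sum_k coupling[k, m] * d[k]`, and
#' `x(t+2dt) = x(t+dt) + g2*dt + e2`, with `e ~ N(0, noise_sd[m]^2)`.
#' All randomness flows from `spec$seed`; draws are made per subject in
#' subject-id order, so output is bit-identical for identical specs.
#'
#' @param spec a [cohort_spec()].
#' @return a [longitudinal_dataset()] with progressors first.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n1 <- spec$n_progressor
  n0 <- spec$n_stable
  n <- n1 + n0
  nm <- spec$n_markers
  labels <- c(rep(1L, n1), rep(0L, n0))
  slope_for <- function(lab) if (lab == 1L) spec$slope_progressor else spec$slope_stable

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  x1 <- matrix(0, n, nm)
  g <- matrix(0, n, nm)
  e1 <- matrix(0, n, nm)
  e2 <- matrix(0, n, nm)
  for (i in seq_len(n)) {
    x1[i, ] <- stats::runif(nm, spec$baseline_ranges[, 1],
                            spec$baseline_ranges[, 2])
    g[i, ] <- stats::rnorm(nm, slope_for(labels[i]), spec$subject_slope_sd)
    e1[i, ] <- stats::rnorm(nm, 0, spec$noise_sd)
    e2[i, ] <- stats::rnorm(nm, 0, spec$noise_sd)
  }
  if (spec$center_slopes) {
    for (lab in c(1L, 0L)) {
      rows <- which(labels == lab)
      centre <- colMeans(g[rows, , drop = FALSE])
      g[rows, ] <- sweep(g[rows, , drop = FALSE], 2, centre) +
        matrix(slope_for(lab), length(rows), nm, byrow = TRUE)
    }
  }

  x2 <- x1 + g * spec$dt + e1
  slope_mat <- t(vapply(labels, slope_for, numeric(nm)))
  if (nm == 1L) slope_mat <- matrix(slope_mat, n, 1L)
  d <- slope_mat - (x2 - x1) / spec$dt        # realized first-interval deviation
  fd <- d %*% spec$coupling_matrix            # column-m convention: fd = mu*' d
  g2 <- slope_mat - fd
  x3 <- x2 + g2 * spec$dt + e2

  values <- array(c(x1, x2, x3), dim = c(n, nm, 3L))
  longitudinal_dataset(values, labels = labels, dt = spec$dt)
}

#' @rdname generate_cohort
#' @param object a [cohort_spec()].
#' @param nsim number of cohorts to simulate.
#' @param seed optional seed overriding `object$seed` (the `k`-th replicate
#'   uses `seed + k - 1`).
#' @param ... ignored.
#' @export
simulate.cohort_spec <- function(object, nsim = 1, seed = NULL, ...) {
  base_seed <- if (is.null(seed)) object$seed else as.integer(seed)
  sims <- lapply(seq_len(nsim), function(k) {
    sp <- object
    sp$seed <- base_seed + k - 1L
    generate_cohort(sp)
  })
  if (nsim == 1L) sims[[1]] else sims
}

#' Latent gradient deviations of a generated cohort
#'
#' Recovers the exact first- and second-interval gradient deviations the
#' generator used (deviations are defined against the class's nominal rate,
#' and are recomputed from the stored readings with the identical arithmetic,
#' so they are bit-identical to the generation-time values).  Intended for
#' parameter-recovery tests: in a noiseless cohort the future-offset matrix
#' equals `offsets %*% coupling_matrix` exactly.
#'
#' @param ds a dataset produced by [generate_cohort()] with `spec`.
#' @param spec the matching [cohort_spec()].
#' @return a list with matrices `offsets` and `future_offsets`, each
#'   `n_subjects x n_markers`.
#' @export
true_offsets <- function(ds, spec) {
  stopifnot(inherits(ds, "longitudinal_dataset"), inherits(spec, "cohort_spec"))
  n <- n_subjects(ds)
  nm <- length(ds$marker_ids)
  if (nm != spec$n_markers ||
      n != spec$n_progressor + spec$n_stable ||
      !isTRUE(all.equal(ds$dt, spec$dt)))
    stop("dataset shape does not match the cohort spec")
  slope_for <- function(lab) if (lab == 1L) spec$slope_progressor else spec$slope_stable
  slope_mat <- t(vapply(ds$labels, slope_for, numeric(nm)))
  if (nm == 1L) slope_mat <- matrix(slope_mat, n, 1L)
  d <- slope_mat - (ds$values[, , 2] - ds$values[, , 1]) / spec$dt
  d <- matrix(d, n, nm)
  fd <- d %*% spec$coupling_matrix
  dimnames(d) <- dimnames(fd) <- list(ds$subject_ids, ds$marker_ids)
  list(offsets = d, future_offsets = fd)
}
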