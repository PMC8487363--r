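# Shared fixtures: small cohorts and hand-built datasets, constructed in code.

# A dataset built directly from a subject x marker x visit array.
make_dataset <- function(values, labels, dt = 1, ...) {
  longitudinal_dataset(values, labels = labels, dt = dt, ...)
}

# Two-subject (one per class), one-marker dataset with prescribed visits.
tiny_two_subject <- function(v1, v0, dt = 1) {
  arr <- array(c(v1[1], v0[1], v1[2], v0[2], v1[3], v0[3]),
               dim = c(2, 1, 3))
  make_dataset(arr, labels = c(1L, 0L), dt = dt)
}

# Exactly linear cohort: class slopes only, no noise, no subject variation.
linear_spec <- function(n1 = 6, n0 = 8, nm = 2, dt = 0.5, seed = 7,
                        slope1 = NULL, slope0 = NULL) {
  cohort_spec(n_progressor = n1, n_stable = n0, n_markers = nm, dt = dt,
              slope_progressor = slope1 %||% rep(-0.2, nm),
              slope_stable = slope0 %||% rep(-0.05, nm),
              subject_slope_sd = 0, noise_sd = 0,
              baseline_ranges = cbind(rep(1, nm), rep(2, nm)),
              seed = seed)
}

# Coupled noiseless cohort: subject-level slope variation drives offsets,
# a known coupling matrix drives second-interval deviations.
coupled_spec <- function(n1 = 25, n0 = 25, nm = 3, dt = 0.5, seed = 11,
                         coupling = NULL, noise_sd = 0,
                         subject_slope_sd = 0.2) {
  if (is.null(coupling)) {
    coupling <- matrix(0, nm, nm)
    coupling[cbind(seq_len(nm), c(seq_len(nm)[-1], 1))] <- 0.4
    diag(coupling) <- 0.25
  }
  cohort_spec(n_progressor = n1, n_stable = n0, n_markers = nm, dt = dt,
              slope_progressor = rep(-0.3, nm),
              slope_stable = rep(-0.1, nm),
              coupling_matrix = coupling,
              subject_slope_sd = subject_slope_sd, noise_sd = noise_sd,
              baseline_ranges = cbind(rep(2, nm), rep(4, nm)),
              seed = seed)
}

# Well-separated noisy cohort for classification checks.
separated_spec <- function(n1 = 60, n0 = 60, nm = 10, dt = 0.5, seed = 3,
                           noise_sd = 0.02, gap = 0.1) {
  cohort_spec(n_progressor = n1, n_stable = n0, n_markers = nm, dt = dt,
              slope_progressor = rep(-0.02 - gap, nm),
              slope_stable = rep(-0.02, nm),
              subject_slope_sd = 0.02, noise_sd = noise_sd,
              baseline_ranges = cbind(rep(0.5, nm), rep(1, nm)),
              seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
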