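# Shared fixtures: everything is generated in code, sized for speed.

# a shortened discrimination protocol (same structure, fewer trials)
small_task_spec <- function(n_trials = 12, rest = 60) {
  task_spec(n_trials_per_session = n_trials, n_sessions = 2,
            rest_block_duration = rest)
}

# a shortened HRF-characterization run
small_hrf_events <- function(n_trials = 8, seed = 1) {
  make_hrf_design(n_trials = n_trials, seed = seed)
}

small_grid <- c(8, 8, 2)

# spatially smooth unit-variance noise map (for permutation calibration)
smooth_noise_map <- function(dims, fwhm = 2.5) {
  b <- bold_series(array(rnorm(prod(dims) * 2), dim = c(dims, 2)),
                   tr = 1, voxel_size = c(1, 1, 1))
  m <- gaussian_smooth(b, fwhm = fwhm)$data[, , , 1]
  (m - mean(m)) / sd(m)
}

# noise-free spec for deterministic-limit checks
tiny_noise <- function() {
  noise_spec(white_sd = 1e-6, ar1_coefficient = 0, drift_amplitude = 0)
}
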