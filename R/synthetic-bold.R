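#' 4D BOLD series container
#'
#' @param data 4D numeric array (x, y, z, time), scanner units or percent.
#' @param tr Repetition time (s, > 0).
#' @param voxel_size Voxel edge lengths (mm), length-3.
#' @param mask Optional logical 3D brain mask with the same spatial shape.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr, voxel_size = c(0.47, 0.47, 1), mask = NULL) {
  if (length(dim(data)) != 4) stop("data must be a 4D array (x, y, z, time)")
  if (dim(data)[4] < 2) stop("time axis must have length >= 2")
  if (!is.numeric(tr) || tr <= 0) stop("TR must be > 0")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)[1:3]))
      stop("mask must match the spatial shape of data")
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  structure(list(data = data, tr = tr, voxel_size = as.numeric(voxel_size),
                 mask = mask),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_series: %d x %d x %d voxels, %d volumes, TR = %g s, voxel %g x %g x %g mm\n",
              d[1], d[2], d[3], d[4], x$tr,
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Noise specification for the BOLD simulator
#'
#' The noise model is AR(1) serial correlation driven by white innovations,
#' plus a slow sinusoidal drift with a random phase per voxel.  Defaults
#' are calibrated so that the pipeline's temporal-SNR map (high-pass at
#' 100 s then spatial smoothing, see [tsnr_map()]) has an in-mask median
#' inside `target_tsnr_range`, matching telencephalic tSNR observed with
#' the awake-pigeon RARE protocol.
#'
#' @param baseline_level Baseline signal (arbitrary scanner units).
#' @param white_sd Innovation standard deviation (same units).
#' @param ar1_coefficient AR(1) coefficient, in \[0, 1).
#' @param drift_amplitude Amplitude of the sinusoidal drift.
#' @param drift_period Drift period (s).
#' @param target_tsnr_range Calibration target for the in-mask median tSNR.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(baseline_level = 1000, white_sd = 17,
                       ar1_coefficient = 0.3, drift_amplitude = 8,
                       drift_period = 120,
                       target_tsnr_range = c(110, 220)) {
  stopifnot(baseline_level > 0, white_sd > 0,
            ar1_coefficient >= 0, ar1_coefficient < 1,
            drift_amplitude >= 0, drift_period > 0)
  structure(list(baseline_level = baseline_level, white_sd = white_sd,
                 ar1_coefficient = ar1_coefficient,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period,
                 target_tsnr_range = target_tsnr_range),
            class = "noise_spec")
}

#' Default ellipsoidal brain mask for a simulation grid
#' @param grid Integer length-3 grid shape.
#' @return Logical 3D array.
#' @export
default_brain_mask <- function(grid = c(16, 16, 4)) {
  cx <- (grid + 1) / 2
  r <- grid / 2
  idx <- expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                     z = seq_len(grid[3]))
  inside <- ((idx$x - cx[1]) / r[1])^2 + ((idx$y - cx[2]) / r[2])^2 +
    ((idx$z - cx[3]) / max(r[3], 1))^2 <= 1
  array(inside, dim = grid)
}

#' Default active blob for a simulation grid
#'
#' A compact box of voxels (roughly 4 x 4 x 2 at the default grid) placed
#' inside the brain mask, standing in for a stimulus-responsive region.
#'
#' @param grid Integer length-3 grid shape.
#' @return Logical 3D array.
#' @export
default_active_mask <- function(grid = c(16, 16, 4)) {
  m <- array(FALSE, dim = grid)
  xr <- seq(max(1, floor(grid[1] / 2) - 1), min(grid[1], floor(grid[1] / 2) + 2))
  yr <- seq(max(1, floor(grid[2] / 2) - 1), min(grid[2], floor(grid[2] / 2) + 2))
  zr <- seq(max(1, floor(grid[3] / 2)), min(grid[3], floor(grid[3] / 2) + 1))
  m[xr, yr, zr] <- TRUE
  m & default_brain_mask(grid)
}

# Boxcar (or impulse) regressor on a fine dt grid convolved with the HRF
# kernel and sampled at volume acquisition times.  Impulses (duration 0)
# are unit-area sticks of height 1/dt.  `normalize = "peak"` scales so an
# isolated event of the given duration peaks at 1 (betas then read as peak
# percent signal change).
hrf_regressor <- function(onsets, durations, hrf, tr, n_volumes, dt = 0.1,
                          normalize = c("none", "peak")) {
  normalize <- match.arg(normalize)
  total <- n_volumes * tr
  nt <- ceiling(total / dt) + 1L
  u <- numeric(nt)
  durations <- rep_len(durations, length(onsets))
  for (i in seq_along(onsets)) {
    if (onsets[i] >= total) next
    i0 <- floor(onsets[i] / dt) + 1L
    if (durations[i] <= 0) {
      u[i0] <- u[i0] + 1 / dt
    } else {
      i1 <- min(nt, ceiling((onsets[i] + durations[i]) / dt))
      u[i0:i1] <- u[i0:i1] + 1
    }
  }
  tk <- seq(0, min(40, total), by = dt)
  k <- double_gamma_kernel(tk, hrf)
  v <- convolve(c(u, numeric(length(k))), rev(k), type = "open")[seq_len(nt)] * dt
  if (normalize == "peak") {
    ref_dur <- max(durations[1], dt)
    pk <- max(hrf_response(hrf, stim_duration = ref_dur, dt = dt,
                           t_max = max(30, ref_dur + 25))$values)
    v <- v / pk
  }
  vol_idx <- pmin(nt, round((seq_len(n_volumes) - 1) * tr / dt) + 1L)
  v[vol_idx]
}

#' Simulate a 4D BOLD run from an event design
#'
#' Forward model: active voxels carry the sum over conditions of
#' `beta[condition]` times the condition boxcar convolved with the true
#' HRF (normalized so an isolated event peaks at 1, i.e. betas are peak
#' percent signal change), riding on the baseline.  Every voxel receives
#' AR(1) noise plus a slow sinusoidal drift with a voxel-specific random
#' phase.
#'
#' @param events An `event_table` (see [make_discrimination_design()]).
#' @param active_mask Logical 3D array of responsive voxels.
#' @param true_params `hrf_params` generating the responses.
#' @param betas Named numeric vector, peak percent signal change per
#'   condition (`trial_type` values present in `events`).
#' @param noise A [noise_spec()].
#' @param tr Repetition time (s); defaults to the event table's.
#' @param grid Length-3 grid shape.
#' @param seed Integer seed.
#' @param brain_mask Optional logical 3D mask; default
#'   [default_brain_mask()].
#' @param voxel_size Voxel size (mm).
#' @return A `bold_series` with the brain mask attached.
#' @export
simulate_bold <- function(events, active_mask = default_active_mask(grid),
                          true_params = canonical_hrf("pigeon"),
                          betas, noise = noise_spec(),
                          tr = attr(events, "tr"), grid = c(16, 16, 4),
                          seed = 1, brain_mask = default_brain_mask(grid),
                          voxel_size = c(0.47, 0.47, 1)) {
  stopifnot(inherits(noise, "noise_spec"))
  if (!identical(dim(active_mask), as.integer(grid)) &&
      !identical(dim(active_mask), grid))
    stop("active_mask shape must match grid")
  if (!all(names(betas) %in% unique(events$trial_type)))
    stop("betas name conditions absent from events: ",
         paste(setdiff(names(betas), unique(events$trial_type)), collapse = ", "))
  n_vol <- attr(events, "n_volumes")
  if (is.null(n_vol)) n_vol <- ceiling(max(events$onset + events$duration) / tr) + 2L
  local_rng(seed)

  # noiseless active-voxel percent-signal time course
  psc <- numeric(n_vol)
  for (cond in names(betas)) {
    sel <- events$trial_type == cond
    reg <- hrf_regressor(events$onset[sel], events$duration[sel],
                         true_params, tr, n_vol, normalize = "peak")
    psc <- psc + betas[[cond]] * reg
  }

  n_vox <- prod(grid)
  base <- noise$baseline_level
  sig <- matrix(base, nrow = n_vol, ncol = n_vox)
  act <- as.vector(active_mask)
  if (any(act))
    sig[, act] <- base * (1 + psc / 100)

  eps <- matrix(rnorm(n_vol * n_vox, sd = noise$white_sd), n_vol, n_vox)
  if (noise$ar1_coefficient > 0)
    eps <- apply(eps, 2, function(e)
      as.numeric(stats::filter(e, noise$ar1_coefficient, method = "recursive")))
  if (noise$drift_amplitude > 0) {
    tvec <- (seq_len(n_vol) - 1) * tr
    phase <- runif(n_vox, 0, 2 * pi)
    drift <- noise$drift_amplitude *
      sin(outer(tvec, rep(2 * pi / noise$drift_period, n_vox)) +
            matrix(phase, n_vol, n_vox, byrow = TRUE))
    eps <- eps + drift
  }
  sig <- sig + eps
  arr <- array(t(sig), dim = c(grid, n_vol))
  bold_series(arr, tr = tr, voxel_size = voxel_size, mask = brain_mask)
}

#' Motion-parameter trace container
#' @param mat Numeric matrix, volumes x 6; columns rot_x, rot_y, rot_z
#'   (radians) then trans_x, trans_y, trans_z (mm).
#' @return Object of class `motion_trace` (a matrix).
#' @export
motion_trace <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 6) stop("motion trace must have 6 columns")
  colnames(mat) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  class(mat) <- c("motion_trace", class(matrix()))
  mat
}

#' Simulate sub-voxel head-motion parameter traces
#'
#' Six smooth, bounded random-walk traces (three rotations, three
#' translations).  Each trace is a moving-average-smoothed random walk
#' rescaled so its maximum absolute excursion is a random fraction
#' (85-100%) of the bound, guaranteeing `max |trace| <= bound` in every
#' draw.  Default bounds match the maximum absolute translation and
#' rotation observed during the colour discrimination experiment.
#'
#' @param n_volumes Number of volumes.
#' @param max_translation Translation bound (mm).
#' @param max_rotation Rotation bound (degrees).
#' @param seed Integer seed.
#' @return A `motion_trace` (rotations stored in radians).
#' @export
simulate_motion <- function(n_volumes, max_translation = 0.048,
                            max_rotation = 0.045, seed = 1) {
  stopifnot(n_volumes >= 2, max_translation >= 0, max_rotation >= 0)
  local_rng(seed)
  bounds <- c(rep(max_rotation * pi / 180, 3), rep(max_translation, 3))
  mat <- sapply(bounds, function(b) {
    if (b == 0) return(numeric(n_volumes))
    w <- cumsum(rnorm(n_volumes))
    w <- as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2))
    w[is.na(w)] <- 0
    w <- w - mean(w)
    m <- max(abs(w))
    if (m == 0) return(numeric(n_volumes))
    w * (b * runif(1, 0.85, 1) / m)
  })
  motion_trace(mat)
}
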