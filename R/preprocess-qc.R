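#' Spatial Gaussian smoothing of a BOLD series
#'
#' Separable per-volume 3D Gaussian smoothing with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` converted to voxel units per axis
#' from the series' voxel size.  The kernel is truncated at 4 sigma and
#' renormalized; boundaries are reflective, so the spatial sum of each
#' volume is preserved.  `fwhm = 0` is the identity.
#'
#' Note on units: the acquisition pipeline states its 8 mm FWHM after
#' relabeling voxel sizes by a factor of 10; in native units that is
#' 0.8 mm, the default here.
#'
#' @param series A `bold_series`.
#' @param fwhm Full-width at half-maximum of the kernel (mm, >= 0).
#' @return A smoothed `bold_series`.
#' @export
gaussian_smooth <- function(series, fwhm = 0.8) {
  stopifnot(inherits(series, "bold_series"))
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(series)
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / series$voxel_size
  d <- dim(series$data)
  out <- series$data
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-6) next
    half <- max(1L, ceiling(4 * s))
    k <- dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    out <- smooth_axis(out, axis, k)
  }
  bold_series(out, tr = series$tr, voxel_size = series$voxel_size,
              mask = series$mask)
}

# Convolve a 4D array along one spatial axis with kernel k, reflective
# boundary, via a dense banded matrix applied to a permuted reshape.
smooth_axis <- function(arr, axis, k) {
  d <- dim(arr)
  n <- d[axis]
  half <- (length(k) - 1L) / 2L
  # half-sample symmetric reflection (0 -> 1, n+1 -> n, ...): with a
  # symmetric kernel the smoothing matrix is symmetric and row
  # stochastic, hence doubly stochastic — both the spatial sum and
  # constant fields are preserved exactly
  refl <- function(i) {
    lo <- i < 1L
    i[lo] <- 1L - i[lo]
    hi <- i > n
    i[hi] <- 2L * n + 1L - i[hi]
    pmin(pmax(i, 1L), n)
  }
  K <- matrix(0, n, n)
  for (off in seq(-half, half)) {
    src <- refl(seq_len(n) + off)
    w <- k[off + half + 1L]
    for (r in seq_len(n)) K[r, src[r]] <- K[r, src[r]] + w
  }
  perm <- c(axis, setdiff(1:4, axis))
  ap <- aperm(arr, perm)
  dim(ap) <- c(n, prod(d[perm[-1]]))
  ap <- K %*% ap
  dim(ap) <- d[perm]
  aperm(ap, order(perm))
}

#' Grand-mean scaling of a BOLD run
#'
#' Multiplies the whole run by the single scalar that makes the 4D
#' in-mask mean equal `target` (default 10000) — global intensity
#' normalization by one multiplicative factor per run.
#'
#' @param series A `bold_series`.
#' @param target Target grand mean.
#' @return A scaled `bold_series`; the factor is stored in attribute
#'   `scale_factor`.
#' @export
grand_mean_scale <- function(series, target = 10000) {
  stopifnot(inherits(series, "bold_series"))
  m <- if (is.null(series$mask)) mean(series$data) else
    mean(series$data[rep(series$mask, dim(series$data)[4])])
  if (!is.finite(m) || m <= 0) stop("in-mask grand mean must be positive")
  f <- target / m
  out <- bold_series(series$data * f, tr = series$tr,
                     voxel_size = series$voxel_size, mask = series$mask)
  attr(out, "scale_factor") <- f
  out
}

# DCT-II basis whose columns have period > cutoff (the drift subspace)
dct_drift_basis <- function(n, tr, cutoff) {
  kmax <- floor(2 * n * tr / cutoff)
  if (kmax < 1) return(NULL)
  tgrid <- seq_len(n) - 0.5
  sapply(seq_len(kmax), function(k) cos(pi * k * tgrid / n))
}

#' High-pass temporal filtering
#'
#' Removes fluctuations slower than `cutoff` by regressing each voxel's
#' time course on a discrete-cosine drift basis (all DCT components with
#' period above the cutoff) and keeping the residual; the temporal mean is
#' restored afterwards.  A linear, idempotent operation with a sharp,
#' testable frequency response.
#'
#' @param series A `bold_series`.
#' @param cutoff Cutoff period (s); must exceed `2 * TR`.
#' @return A filtered `bold_series`.
#' @export
highpass_filter <- function(series, cutoff = 60) {
  stopifnot(inherits(series, "bold_series"))
  tr <- series$tr
  if (cutoff <= 2 * tr) stop("cutoff must exceed 2 * TR")
  d <- dim(series$data)
  n <- d[4]
  X <- dct_drift_basis(n, tr, cutoff)
  if (is.null(X)) return(series)
  Y <- matrix(series$data, ncol = n)          # voxels x time
  Yt <- t(Y)                                  # time x voxels
  mu <- colMeans(Yt)
  fit <- qr.fitted(qr(cbind(1, X)), Yt)
  res <- Yt - fit
  out <- sweep(res, 2, mu, `+`)
  arr <- array(t(out), dim = d)
  bold_series(arr, tr = tr, voxel_size = series$voxel_size,
              mask = series$mask)
}

# Legendre-like orthogonal polynomial basis on [-1, 1], degrees 0..order
poly_basis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  X <- matrix(1, n, 1)
  if (order >= 1) X <- cbind(X, stats::poly(x, degree = order))
  X
}

#' Project polynomial trends out of a time course
#'
#' Least-squares projection of the samples onto the orthogonal complement
#' of polynomials in time up to the given order (orthogonal basis on
#' \[-1, 1\]); used to characterize the baseline before percent-signal
#' conversion.
#'
#' @param timecourse A `sampled_curve` (or numeric vector).
#' @param order Polynomial order (>= 0).  Order 0 removes the mean.
#' @return A `sampled_curve` of residuals.
#' @export
project_out_polynomials <- function(timecourse, order = 2) {
  v <- if (inherits(timecourse, "sampled_curve")) timecourse$values else as.numeric(timecourse)
  if (order < 0) stop("order must be >= 0")
  if (length(v) <= order + 1) stop("time course too short for polynomial order ", order)
  X <- poly_basis(length(v), order)
  res <- v - qr.fitted(qr(X), v)
  if (inherits(timecourse, "sampled_curve"))
    sampled_curve(res, dt = timecourse$dt, t0 = timecourse$t0)
  else res
}

#' Percent signal change, trial-locked
#'
#' For each stimulus onset, the baseline `b` is the mean over
#' `[onset - baseline_window, onset)`; the peri-stimulus epoch is
#' converted to `100 * (x - b) / b` and returned time-locked to onset.
#'
#' @param timecourse A `sampled_curve` with `t0` giving run-clock time of
#'   the first sample (usually 0).
#' @param stimulus_onsets Onset times (s, run clock).
#' @param baseline_window Baseline window length before onset (s).
#' @param epoch Length of the returned peri-stimulus epoch (s).
#' @return A list of per-trial `sampled_curve`s (t0 = 0 at stimulus
#'   onset); trials whose epoch exceeds the run are dropped with a
#'   warning.
#' @export
percent_signal_change <- function(timecourse, stimulus_onsets,
                                  baseline_window = 2, epoch = 30) {
  stopifnot(inherits(timecourse, "sampled_curve"))
  v <- timecourse$values
  dt <- timecourse$dt
  times <- curve_times(timecourse)
  out <- list()
  dropped <- 0L
  for (j in seq_along(stimulus_onsets)) {
    on <- stimulus_onsets[j]
    bsel <- which(times >= on - baseline_window - 1e-9 & times < on - 1e-9)
    esel <- which(times >= on - 1e-9 & times <= on + epoch + 1e-9)
    if (length(bsel) < 1) stop("no baseline samples for trial ", j)
    if (length(esel) < round(epoch / dt)) { dropped <- dropped + 1L; next }
    b <- mean(v[bsel])
    if (!is.finite(b) || b == 0) stop("zero baseline mean for trial ", j)
    out[[length(out) + 1L]] <-
      sampled_curve(100 * (v[esel] - b) / b, dt = dt,
                    t0 = times[esel[1]] - on)
  }
  if (dropped > 0)
    warning(dropped, " trial(s) dropped: epoch exceeds run end")
  attr(out, "n_dropped") <- dropped
  out
}

#' Temporal signal-to-noise ratio map
#'
#' Per-voxel temporal mean divided by temporal standard deviation.  Callers
#' compose the acquisition pipeline's order (high-pass filter at 100 s,
#' then spatial smoothing) before calling.  Zero-variance voxels receive an
#' `Inf` sentinel and are flagged in attribute `flagged`.
#'
#' @param series A `bold_series` (already filtered/smoothed by the caller).
#' @return A 3D numeric map with attribute `flagged` (logical 3D array).
#' @export
tsnr_map <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  d <- dim(series$data)
  Y <- matrix(series$data, ncol = d[4])
  mu <- rowMeans(Y)
  sd_ <- sqrt(rowSums((Y - mu)^2) / (d[4] - 1))
  tsnr <- ifelse(sd_ == 0, Inf, mu / sd_)
  map <- array(tsnr, dim = d[1:3])
  attr(map, "flagged") <- array(sd_ == 0, dim = d[1:3])
  map
}

#' Pipeline tSNR: high-pass filter then smooth, then map
#'
#' Convenience composition matching the QC definition used for the awake
#' protocol: high-pass at `cutoff` (100 s), spatial smoothing at `fwhm`,
#' then [tsnr_map()].
#'
#' @param series A raw `bold_series`.
#' @param cutoff High-pass cutoff (s).
#' @param fwhm Smoothing FWHM (mm).
#' @return A tSNR map (see [tsnr_map()]).
#' @export
tsnr_pipeline <- function(series, cutoff = 100, fwhm = 0.8) {
  tsnr_map(gaussian_smooth(highpass_filter(series, cutoff = cutoff),
                           fwhm = fwhm))
}

#' Median absolute deviation (no consistency scaling)
#'
#' `median(|x_i - median(x)|)` — the robust dispersion statistic used for
#' motion QC.  No Gaussian consistency constant is applied.
#'
#' @param values Numeric vector (length >= 1).
#' @return The MAD.
#' @export
#' @examples
#' mad_stat(c(1, 2, 3, 4, 5))  # 1
mad_stat <- function(values) {
  if (length(values) < 1) stop("mad_stat requires at least one value")
  if (anyNA(values)) stop("mad_stat: values contain NA")
  stats::mad(values, constant = 1)
}

#' Motion QC summary
#'
#' Per-column MAD and maximum absolute excursion of a motion trace,
#' plus the overall maxima for translations (mm) and rotations
#' (reported in degrees).
#'
#' @param motion A `motion_trace`.
#' @return A data frame with one row per parameter and attributes
#'   `max_translation_mm`, `max_rotation_deg`.
#' @export
motion_qc <- function(motion) {
  stopifnot(inherits(motion, "motion_trace"))
  df <- data.frame(parameter = colnames(motion),
                   mad = apply(motion, 2, mad_stat),
                   max_abs = apply(abs(motion), 2, max),
                   row.names = NULL)
  attr(df, "max_translation_mm") <- max(abs(motion[, 4:6]))
  attr(df, "max_rotation_deg") <- max(abs(motion[, 1:3])) * 180 / pi
  df
}
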