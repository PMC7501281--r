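#' Hemodynamic response function parameters
#'
#' Container for the five shape parameters plus amplitude of the
#' double-gamma HRF model
#' \deqn{h(t) = A\left(\frac{t^{\alpha_1-1}\beta_1^{\alpha_1}e^{-\beta_1 t}}
#'   {\Gamma(\alpha_1)} -
#'   c\,\frac{t^{\alpha_2-1}\beta_2^{\alpha_2}e^{-\beta_2 t}}
#'   {\Gamma(\alpha_2)}\right),\quad t \ge 0,}
#' i.e. a unit-mass gamma density response minus a scaled unit-mass gamma
#' density undershoot.
#'
#' @param alpha1 Shape of the response gamma (dimensionless, > 1).
#' @param alpha2 Shape of the undershoot gamma (dimensionless, > 1).
#' @param beta1 Rate of the response gamma (1/s, > 0).
#' @param beta2 Rate of the undershoot gamma (1/s, > 0).
#' @param c Undershoot-to-response ratio, in \[0, 1\].
#' @param A Amplitude scale (percent-signal-change units), default 1.
#' @return An object of class `hrf_params`.
#' @seealso [canonical_hrf()] for the standard human and pigeon sets.
#' @export
#' @examples
#' hrf_params(7.71, 11.48, 1.74, 0.74, 0.25)
hrf_params <- function(alpha1, alpha2, beta1, beta2, c, A = 1) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1,
            beta2 = beta2, c = c, A = A)
  validate_hrf_params(p)
  structure(p, class = "hrf_params")
}

validate_hrf_params <- function(p) {
  need <- c("alpha1", "alpha2", "beta1", "beta2", "c", "A")
  if (!all(need %in% names(p)))
    stop("hrf_params requires fields: ", paste(need, collapse = ", "))
  v <- unlist(p[need])
  if (!all(is.finite(v))) stop("all HRF parameters must be finite")
  if (p$alpha1 <= 1 || p$alpha2 <= 1)
    stop("gamma shapes alpha1, alpha2 must be > 1")
  if (p$beta1 <= 0 || p$beta2 <= 0)
    stop("gamma rates beta1, beta2 must be > 0")
  if (p$c < 0 || p$c > 1) stop("undershoot ratio c must lie in [0, 1]")
  invisible(p)
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf(
    "HRF parameters: alpha1 = %g, alpha2 = %g, beta1 = %g 1/s, beta2 = %g 1/s, c = %g, A = %g\n",
    x$alpha1, x$alpha2, x$beta1, x$beta2, x$c, x$A))
  invisible(x)
}

#' Canonical HRF parameter sets by species
#'
#' `"human"` returns the default double-gamma parameters used by standard
#' fMRI packages (alpha1 = 6, alpha2 = 16, beta1 = beta2 = 1, c = 1/6).
#' `"pigeon"` returns the best-fit parameters estimated from awake-pigeon
#' entopallium responses to 2-s visual stimuli
#' (alpha1 = 7.71, alpha2 = 11.48, beta1 = 1.74, beta2 = 0.74, c = 0.25).
#'
#' @param species `"human"` or `"pigeon"`.
#' @return An `hrf_params` object with `A = 1`.
#' @export
#' @examples
#' canonical_hrf("pigeon")
canonical_hrf <- function(species = c("pigeon", "human")) {
  if (!is.character(species) || length(species) != 1 ||
      !species %in% c("pigeon", "human"))
    stop("unknown species '", paste(species, collapse = ","),
         "'; valid labels: pigeon, human")
  switch(species,
         human  = hrf_params(6, 16, 1, 1, 1 / 6),
         pigeon = hrf_params(7.71, 11.48, 1.74, 0.74, 0.25))
}

#' Evaluate the double-gamma HRF kernel
#'
#' The impulse-response kernel: difference of two gamma densities scaled by
#' amplitude `A`, zero for `t < 0`.  With `strict_gamma_norm = TRUE` the
#' undershoot density is normalized by `gamma(alpha1)` instead of
#' `gamma(alpha2)`; the default unit-mass normalization is the only one
#' under which both terms integrate to 1.
#'
#' @param t Numeric vector of times (s); must be finite.
#' @param p An `hrf_params` object (or a list with the same fields).
#' @param strict_gamma_norm Normalize the undershoot term by
#'   `gamma(alpha1)` rather than `gamma(alpha2)`.  Default `FALSE`.
#' @return Kernel values, same length as `t`.
#' @export
double_gamma_kernel <- function(t, p, strict_gamma_norm = FALSE) {
  validate_hrf_params(p)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("t must be finite numeric")
  pos <- dgamma(pmax(t, 0), shape = p$alpha1, rate = p$beta1)
  und <- dgamma(pmax(t, 0), shape = p$alpha2, rate = p$beta2)
  if (strict_gamma_norm)
    und <- und * gamma(p$alpha2) / gamma(p$alpha1)
  out <- p$A * (pos - p$c * und)
  out[t < 0] <- 0
  out
}

#' Sampled signal curve
#'
#' A regularly sampled time course with sampling interval `dt` (s) and time
#' of the first sample `t0` relative to stimulus onset.
#'
#' @param values Numeric samples (percent signal change or signal units).
#' @param dt Sampling interval (s, > 0).
#' @param t0 Time of first sample relative to stimulus onset (s).
#' @param sem Optional per-sample standard error (same length).
#' @return An object of class `sampled_curve`.
#' @export
sampled_curve <- function(values, dt, t0 = 0, sem = NULL) {
  if (!is.numeric(values) || length(values) < 2)
    stop("values must be numeric of length >= 2")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0")
  if (!is.null(sem) && length(sem) != length(values))
    stop("sem must match values in length")
  structure(list(values = as.numeric(values), dt = dt, t0 = t0, sem = sem),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("sampled_curve: %d samples, dt = %g s, t0 = %g s, range [%.4g, %.4g]\n",
              length(x$values), x$dt, x$t0, min(x$values), max(x$values)))
  invisible(x)
}

#' Time axis of a sampled curve
#' @param curve A `sampled_curve`.
#' @return Numeric vector of sample times (s).
#' @export
curve_times <- function(curve) {
  curve$t0 + (seq_along(curve$values) - 1) * curve$dt
}

#' HRF response to a boxcar stimulus
#'
#' Discrete convolution of a unit boxcar of the given duration with the
#' double-gamma kernel, scaled by `dt` (so the result approximates the
#' continuous convolution).  The curve starts at 0 at `t = 0`.
#'
#' @param p An `hrf_params` object.
#' @param stim_duration Stimulus duration (s, > 0); 2 s in the colour
#'   stimulation protocol.
#' @param dt Sampling interval (s); keep at or below 0.1 s for accurate
#'   peak/width features.  Default 0.01.
#' @param t_max End of the sampled window (s); must be at least
#'   `stim_duration`.  Default 30.
#' @param strict_gamma_norm Passed to [double_gamma_kernel()].
#' @return A `sampled_curve` on `[0, t_max]`.
#' @export
#' @examples
#' r <- hrf_response(canonical_hrf("pigeon"), stim_duration = 2)
#' hdr_features(r)
hrf_response <- function(p, stim_duration, dt = 0.01, t_max = 30,
                         strict_gamma_norm = FALSE) {
  validate_hrf_params(p)
  if (stim_duration <= 0) stop("stim_duration must be > 0")
  if (t_max < stim_duration) stop("t_max must be >= stim_duration")
  t <- seq(0, t_max, by = dt)
  k <- double_gamma_kernel(t, p, strict_gamma_norm = strict_gamma_norm)
  nbox <- max(1L, round(stim_duration / dt))
  box <- rep(1, nbox)
  # full linear convolution, truncated to the sampling window
  v <- convolve(k, rev(box), type = "open")[seq_along(t)] * dt
  sampled_curve(v, dt = dt, t0 = 0)
}

#' Summary features of a hemodynamic response
#'
#' Height `H` (maximum value), time-to-peak `T` (time of the maximum,
#' relative to stimulus onset) and full-width at half-maximum `W` of the
#' main positive lobe, with the two half-maximum crossings located by
#' linear interpolation between samples.  The post-peak undershoot is
#' excluded from `W` by construction (the falling crossing is the first
#' drop below half-maximum after the peak).
#'
#' @param curve A `sampled_curve` with a strictly positive maximum.
#' @return A list with fields `H` (percent signal change), `T` (s),
#'   `W` (s), of class `hdr_features`.
#' @export
hdr_features <- function(curve) {
  stopifnot(inherits(curve, "sampled_curve") || is.list(curve))
  v <- curve$values
  t <- curve_times(curve)
  if (max(v) <= 0) stop("no positive response: curve maximum is <= 0")
  i_pk <- which.max(v)
  H <- v[i_pk]
  half <- H / 2
  # rising crossing: last sample below half before the peak
  before <- which(v[seq_len(i_pk)] < half)
  if (length(before) == 0) {
    t_rise <- t[1]
  } else {
    i <- max(before)
    t_rise <- t[i] + (half - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  # falling crossing: first sample below half after the peak
  after <- which(v[seq(i_pk, length(v))] < half)
  if (length(after) == 0) {
    t_fall <- t[length(t)]
  } else {
    j <- i_pk + min(after) - 1L
    t_fall <- t[j - 1] + (half - v[j - 1]) / (v[j] - v[j - 1]) * (t[j] - t[j - 1])
  }
  structure(list(H = H, T = t[i_pk], W = t_fall - t_rise),
            class = "hdr_features")
}

#' @export
print.hdr_features <- function(x, ...) {
  cat(sprintf("HDR features: H = %.4g %%, T = %.3g s, W = %.3g s\n",
              x$H, x$T, x$W))
  invisible(x)
}

#' Serialize HRF parameters to a key-value list
#' @param p An `hrf_params` object.
#' @return A named list with keys alpha1, alpha2, beta1, beta2, c, A.
#' @export
hrf_params_to_list <- function(p) {
  validate_hrf_params(p)
  lapply(unclass(p), as.numeric)
}

#' Deserialize HRF parameters from a key-value list
#' @param x A named list or vector with keys alpha1..c and optionally A.
#' @return An `hrf_params` object.
#' @export
hrf_params_from_list <- function(x) {
  x <- as.list(x)
  if (is.null(x$A)) x$A <- 1
  hrf_params(as.numeric(x$alpha1), as.numeric(x$alpha2),
             as.numeric(x$beta1), as.numeric(x$beta2),
             as.numeric(x$c), as.numeric(x$A))
}
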