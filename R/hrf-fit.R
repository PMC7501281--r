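# t statistic -> z score through the matching normal quantile, stable in
# both tails via log-scale probabilities
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- qnorm(pt(t[pos], df, lower.tail = FALSE, log.p = TRUE),
                  lower.tail = FALSE, log.p = TRUE)
  z[!pos] <- -qnorm(pt(-t[!pos], df, lower.tail = FALSE, log.p = TRUE),
                    lower.tail = FALSE, log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}

#' Localizer GLM: light-responsive voxels from the first run
#'
#' OLS fit of red/green stimulus regressors (boxcars convolved with the
#' human canonical double-gamma HRF — the standard heuristic before the
#' species-specific HRF exists) plus polynomial drift terms; returns the
#' voxelwise z map for the sum contrast (all light vs rest).
#'
#' @param series A `bold_series` (HRF-characterization run).
#' @param events An `event_table` with `trial_type` in red/green.
#' @param hrf The HRF used for the localizer; default human canonical.
#' @param drift_order Polynomial drift order. Default 2.
#' @return A 3D z map (attributes `dof`, `design`).
#' @export
localizer_glm <- function(series, events, hrf = canonical_hrf("human"),
                          drift_order = 2) {
  stopifnot(inherits(series, "bold_series"))
  conds <- intersect(c("red", "green"), unique(events$trial_type))
  if (length(conds) == 0) stop("events contain no red/green trials")
  n_vol <- dim(series$data)[4]
  task <- sapply(conds, function(cc) {
    sel <- events$trial_type == cc
    hrf_regressor(events$onset[sel], events$duration[sel], hrf,
                  series$tr, n_vol)
  })
  X <- cbind(poly_basis(n_vol, drift_order), task)
  colnames(X) <- c("intercept",
                   if (drift_order >= 1) paste0("poly", seq_len(drift_order)),
                   conds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("localizer design matrix is rank deficient")
  Y <- t(matrix(series$data, ncol = n_vol))        # time x voxels
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  dof <- n_vol - ncol(X)
  sigma2 <- colSums(res^2) / dof
  cvec <- as.numeric(colnames(X) %in% conds)
  XtXinv <- chol2inv(qr.R(qx))
  cv <- drop(t(cvec) %*% XtXinv %*% cvec)
  tmap <- drop(cvec %*% beta) / sqrt(cv * sigma2)
  z <- array(t_to_z(tmap, dof), dim = dim(series$data)[1:3])
  attr(z, "dof") <- dof
  attr(z, "design") <- X
  z
}

#' Threshold a z map into a region-of-interest mask
#'
#' @param zmap 3D z map.
#' @param z_threshold Finite threshold; voxels with `z >= z_threshold`
#'   enter the mask.
#' @return A logical 3D array of class `roi_mask` with attribute
#'   `provenance`.
#' @export
select_roi <- function(zmap, z_threshold = 3.1) {
  if (!is.finite(z_threshold)) z_threshold <- -Inf
  m <- zmap >= z_threshold
  if (!any(m)) stop("no activated voxels at threshold z >= ", z_threshold)
  m <- array(m, dim = dim(zmap))
  attr(m, "provenance") <- list(threshold = z_threshold,
                                contrast = "localizer all-light vs rest")
  class(m) <- c("roi_mask", class(m))
  m
}

# ROI-mean time course of a run as a sampled_curve on the run clock
roi_timecourse <- function(series, roi) {
  d <- dim(series$data)
  Y <- matrix(series$data, ncol = d[4])
  sampled_curve(colMeans(Y[as.vector(roi), , drop = FALSE]),
                dt = series$tr, t0 = 0)
}

#' Trial-averaged hemodynamic response within an ROI
#'
#' Per run: ROI-mean time course, polynomial trends projected out (signal
#' level restored so percent conversion is well defined), percent signal
#' change per trial, then trial average.  Runs are then averaged with the
#' per-timepoint SEM computed across runs.
#'
#' @param series_list List of `bold_series`, one per run.
#' @param events_list List of matching `event_table`s.
#' @param roi A logical 3D mask (e.g. from [select_roi()]).
#' @param detrend_order Polynomial detrend order. Default 2.
#' @param baseline_window Baseline window before onset (s). Default 2.
#' @param epoch Peri-stimulus epoch length (s). Default 30.
#' @param trial_types Optional subset of `trial_type`s to average.
#' @return A `sampled_curve` (dt = TR, t0 = 0) with `sem` across runs and
#'   attribute `n_runs`.
#' @export
extract_average_hdr <- function(series_list, events_list, roi,
                                detrend_order = 2, baseline_window = 2,
                                epoch = 30, trial_types = NULL) {
  if (length(series_list) < 1) stop("need at least one run")
  if (length(series_list) != length(events_list))
    stop("series_list and events_list lengths differ")
  if (!any(roi)) stop("ROI mask is empty")
  run_means <- list()
  for (r in seq_along(series_list)) {
    tc <- roi_timecourse(series_list[[r]], roi)
    lev <- mean(tc$values)
    det <- project_out_polynomials(tc, detrend_order)
    det$values <- det$values + lev      # restore baseline level
    ev <- events_list[[r]]
    onsets <- if (is.null(trial_types)) ev$onset else
      ev$onset[ev$trial_type %in% trial_types]
    trials <- percent_signal_change(det, onsets,
                                    baseline_window = baseline_window,
                                    epoch = epoch)
    if (length(trials) == 0) stop("run ", r, ": no usable trials")
    m <- rowMeans(sapply(trials, `[[`, "values"))
    run_means[[r]] <- m
  }
  M <- sapply(run_means, identity)
  avg <- rowMeans(M)
  sem <- if (ncol(M) > 1) apply(M, 1, sd) / sqrt(ncol(M)) else rep(0, nrow(M))
  out <- sampled_curve(avg, dt = series_list[[1]]$tr, t0 = 0, sem = sem)
  attr(out, "n_runs") <- length(series_list)
  out
}

#' Default parameter bounds for HRF fitting
#'
#' A plausible range wide enough to contain both the human canonical and
#' the pigeon best-fit parameter sets with margin.
#' @return A list with `lower` and `upper` named vectors over
#'   (A, alpha1, alpha2, beta1, beta2, c).
#' @export
hrf_fit_bounds <- function() {
  list(lower = c(A = 1e-4, alpha1 = 2, alpha2 = 2, beta1 = 0.2,
                 beta2 = 0.1, c = 0),
       upper = c(A = 100, alpha1 = 14, alpha2 = 25, beta1 = 4,
                 beta2 = 3, c = 1))
}

# model prediction at the sample times of `curve`: the boxcar-kernel
# convolution has the closed form
#   A [ (G1(t) - G1(t - d)) - c (G2(t) - G2(t - d)) ]
# with G1, G2 the gamma CDFs, exact at any t (no discretization error)
hrf_model_at <- function(theta, times, stim_duration) {
  tm <- pmax(times, 0)
  tl <- pmax(times - stim_duration, 0)
  v <- theta[["A"]] *
    ((pgamma(tm, theta[["alpha1"]], theta[["beta1"]]) -
        pgamma(tl, theta[["alpha1"]], theta[["beta1"]])) -
       theta[["c"]] *
       (pgamma(tm, theta[["alpha2"]], theta[["beta2"]]) -
          pgamma(tl, theta[["alpha2"]], theta[["beta2"]])))
  v * (times >= 0)
}

#' Fit the double-gamma HRF model to a measured response curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints) of the 2-s-boxcar-convolved double-gamma model to a
#' trial-averaged percent-signal-change curve, over
#' (A, alpha1, alpha2, beta1, beta2, c).  Multi-start with log-uniformly
#' jittered initializations guards against local minima; the best
#' residual sum of squares wins.  95% confidence intervals come from the
#' linearized covariance at the optimum (finite-difference Jacobian).
#'
#' @param curve A `sampled_curve` covering at least 20 s post onset.
#' @param stim_duration Stimulus duration convolved into the model (s).
#' @param bounds A list with `lower`/`upper` named vectors; default
#'   [hrf_fit_bounds()].
#' @param init Initial `hrf_params`; default human canonical.
#' @param n_starts Number of multi-start initializations. Default 10.
#' @param seed Integer seed for the jitter.
#' @return An object of class `hrf_fit_result`: fields `params`
#'   (`hrf_params`), `ci95` (parameter x lower/upper matrix), `rss`,
#'   `n_points`, `at_bound` (logical per parameter), `fitted`
#'   (`sampled_curve`).
#' @export
fit_hrf <- function(curve, stim_duration = 2, bounds = hrf_fit_bounds(),
                    init = canonical_hrf("human"), n_starts = 10,
                    seed = 1) {
  stopifnot(inherits(curve, "sampled_curve"))
  times <- curve_times(curve)
  if (max(times) < 20) stop("curve must cover at least 20 s post onset")
  y <- curve$values
  lower <- bounds$lower
  upper <- bounds$upper
  pnames <- names(lower)
  th0 <- c(A = NA_real_, alpha1 = init$alpha1, alpha2 = init$alpha2,
           beta1 = init$beta1, beta2 = init$beta2, c = init$c)
  # amplitude start: match observed peak to the init-shape model peak
  pk0 <- max(hrf_model_at(c(th0[-1], A = 1)[pnames], times, stim_duration))
  th0[["A"]] <- max(max(y) / max(pk0, 1e-9), lower[["A"]])
  if (!all(th0[pnames] >= lower & th0[pnames] <= upper))
    stop("bounds must contain the initial parameter values")
  local_rng(seed)
  resid_fn <- function(theta) {
    names(theta) <- pnames
    y - hrf_model_at(theta, times, stim_duration)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- th0[pnames]
    if (s > 1) {
      jit <- exp(runif(5, log(0.6), log(1 / 0.6)))
      start[c("A", "alpha1", "alpha2", "beta1", "beta2")] <-
        start[c("A", "alpha1", "alpha2", "beta1", "beta2")] * jit
      start[["c"]] <- runif(1, lower[["c"]], upper[["c"]])
      start <- pmin(pmax(start, lower), upper)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("HRF fit failed to converge from any of ", n_starts, " starts")
  est <- best$fit$par
  names(est) <- pnames
  n <- length(y)
  p <- length(est)
  sigma2 <- best$rss / max(n - p, 1)
  # finite-difference Jacobian of the model at the optimum
  J <- sapply(pnames, function(nm) {
    h <- max(1e-5, 1e-5 * abs(est[[nm]]))
    up <- est; up[[nm]] <- min(est[[nm]] + h, upper[[nm]])
    dn <- est; dn[[nm]] <- max(est[[nm]] - h, lower[[nm]])
    (hrf_model_at(up, times, stim_duration) -
       hrf_model_at(dn, times, stim_duration)) / (up[[nm]] - dn[[nm]])
  })
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  ci <- matrix(NA_real_, p, 2, dimnames = list(pnames, c("lower", "upper")))
  if (!is.null(cov)) {
    se <- sqrt(pmax(diag(cov), 0))
    tq <- qt(0.975, max(n - p, 1))
    ci[, 1] <- est - tq * se
    ci[, 2] <- est + tq * se
  }
  at_bound <- est <= lower + 1e-8 | est >= upper - 1e-8
  params <- hrf_params(est[["alpha1"]], est[["alpha2"]], est[["beta1"]],
                       est[["beta2"]], est[["c"]], A = est[["A"]])
  fitted <- sampled_curve(hrf_model_at(est, times, stim_duration),
                          dt = curve$dt, t0 = curve$t0)
  structure(list(params = params, ci95 = ci, rss = best$rss,
                 n_points = n, at_bound = at_bound, fitted = fitted),
            class = "hrf_fit_result")
}

#' @export
print.hrf_fit_result <- function(x, ...) {
  cat("Double-gamma HRF fit\n")
  est <- unlist(x$params)[rownames(x$ci95)]
  for (nm in rownames(x$ci95))
    cat(sprintf("  %-6s %8.3f  [%.3f, %.3f]%s\n", nm, est[[nm]],
                x$ci95[nm, 1], x$ci95[nm, 2],
                if (x$at_bound[[nm]]) "  (at bound)" else ""))
  cat(sprintf("  RSS %.4g over %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' Parameter-recovery simulation for the HRF fit
#'
#' Repeats the characterization experiment in silico: the double-gamma
#' response of `true_params` to a `stim_duration` boxcar is sampled at
#' the characterization TR, i.i.d. Gaussian noise with standard
#' deviation `noise_frac` of the peak is added (emulating the residual
#' noise of a ~60-trial average), and [fit_hrf()] is run on each
#' replicate.
#'
#' @param n_replicates Number of simulated averaged curves. Default 50.
#' @param true_params Generating parameters; default pigeon best fit.
#' @param tr Sampling interval of the simulated curves (s). Default 2.
#' @param t_max Curve length (s). Default 30.
#' @param noise_frac Noise SD as a fraction of the peak. Default 0.05.
#' @param stim_duration Stimulus duration (s). Default 2.
#' @param n_starts Multi-starts per fit. Default 10.
#' @param seed Integer seed.
#' @return A matrix (replicates x parameters A, alpha1, alpha2, beta1,
#'   beta2, c) of recovered estimates.
#' @export
hrf_recovery_experiment <- function(n_replicates = 50,
                                    true_params = canonical_hrf("pigeon"),
                                    tr = 2, t_max = 30, noise_frac = 0.05,
                                    stim_duration = 2, n_starts = 10,
                                    seed = 1) {
  local_rng(seed)
  tt <- seq(0, t_max, by = tr)
  theta <- c(A = true_params$A, alpha1 = true_params$alpha1,
             alpha2 = true_params$alpha2, beta1 = true_params$beta1,
             beta2 = true_params$beta2, c = true_params$c)
  clean <- hrf_model_at(theta, tt, stim_duration)
  pk <- max(clean)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  out <- t(vapply(seq_len(n_replicates), function(i) {
    set.seed(sub_seeds[i])
    y <- clean + rnorm(length(tt), sd = noise_frac * pk)
    fit <- fit_hrf(sampled_curve(y, dt = tr, t0 = 0),
                   stim_duration = stim_duration, n_starts = n_starts,
                   seed = sub_seeds[i])
    unlist(fit$params)[c("A", "alpha1", "alpha2", "beta1", "beta2", "c")]
  }, numeric(6)))
  colnames(out) <- c("A", "alpha1", "alpha2", "beta1", "beta2", "c")
  out
}
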