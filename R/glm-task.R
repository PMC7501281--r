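#' Build the first-level design matrix for the Go/NoGo task
#'
#' Seven task regressors — Hit, Miss, CR, FA stimulus windows (2 s
#' boxcars split by trial outcome), reward (1 s boxcar on rewarded
#' trials), post-reward window (4 s after reward offset on rewarded
#' trials; 5 s after stimulus offset on NoGo and unrewarded trials), and
#' mandibulation onsets during rest/ITI outside the post-reward window
#' (impulse events) — each convolved with the supplied HRF on a 0.1 s
#' grid and sampled at the TR grid; plus six demeaned motion nuisance
#' columns and an intercept.  Event types absent from the session are
#' dropped with a warning and recorded in attribute `dropped`.
#'
#' @param events An `event_table` from [make_discrimination_design()].
#' @param trial_labels Character vector, one of Hit/Miss/CR/FA per trial.
#' @param mandib_times All detected mandibulation onset times (s); the
#'   rest/ITI regressor keeps those outside trial and post-reward epochs.
#' @param motion A `motion_trace` with `n_volumes` rows (or NULL).
#' @param hrf `hrf_params` used for convolution; default pigeon.
#' @param tr Repetition time (s); default from `events`.
#' @param n_volumes Number of volumes; default from `events`.
#' @return A matrix of class `design_matrix` with attributes `tr`,
#'   `task_columns`, `dropped`.
#' @export
build_design_matrix <- function(events, trial_labels, mandib_times = numeric(0),
                                motion = NULL, hrf = canonical_hrf("pigeon"),
                                tr = attr(events, "tr"),
                                n_volumes = attr(events, "n_volumes")) {
  if (length(trial_labels) != nrow(events))
    stop("trial_labels length (", length(trial_labels),
         ") must match number of trials (", nrow(events), ")")
  bad <- setdiff(unique(trial_labels), c("Hit", "Miss", "CR", "FA"))
  if (length(bad)) stop("unknown trial labels: ", paste(bad, collapse = ", "))
  if (!is.null(motion) && nrow(motion) != n_volumes)
    stop("motion trace length must equal n_volumes")
  stim_dur <- attr(events, "stimulus_duration")
  rdelay <- attr(events, "reward_delay")
  rdur <- attr(events, "reward_duration")
  post_go <- attr(events, "post_reward_go")
  post_nogo <- attr(events, "post_reward_nogo")

  onset <- events$onset
  rewarded <- trial_labels == "Hit"
  # epochs per trial
  reward_on <- onset + stim_dur + rdelay
  post_on <- ifelse(rewarded, reward_on + rdur, onset + stim_dur)
  post_dur <- ifelse(rewarded, post_go, post_nogo)

  spec <- list(
    Hit  = list(on = onset[trial_labels == "Hit"],  dur = stim_dur),
    Miss = list(on = onset[trial_labels == "Miss"], dur = stim_dur),
    CR   = list(on = onset[trial_labels == "CR"],   dur = stim_dur),
    FA   = list(on = onset[trial_labels == "FA"],   dur = stim_dur),
    reward = list(on = reward_on[rewarded], dur = rdur),
    post_reward = list(on = post_on, dur = post_dur))

  # mandibulation events outside trial epochs and post-reward windows
  if (length(mandib_times)) {
    trial_end <- post_on + post_dur
    in_task <- vapply(mandib_times, function(tt)
      any(tt >= onset & tt < trial_end), logical(1))
    spec$mandib_rest <- list(on = mandib_times[!in_task], dur = 0)
  } else spec$mandib_rest <- list(on = numeric(0), dur = 0)

  cols <- list()
  dropped <- character(0)
  for (nm in names(spec)) {
    if (length(spec[[nm]]$on) == 0) {
      dropped <- c(dropped, nm)
      next
    }
    cols[[nm]] <- hrf_regressor(spec[[nm]]$on, spec[[nm]]$dur, hrf, tr,
                                n_volumes)
  }
  if (length(dropped))
    warning("design columns dropped (no events): ",
            paste(dropped, collapse = ", "))
  X <- do.call(cbind, cols)
  task_cols <- colnames(X) <- names(cols)
  if (!is.null(motion)) {
    M <- sweep(unclass(motion), 2, colMeans(motion))
    colnames(M) <- colnames(motion)
    X <- cbind(X, M)
  }
  X <- cbind(X, intercept = 1)
  attr(X, "tr") <- tr
  attr(X, "task_columns") <- task_cols
  attr(X, "dropped") <- dropped
  class(X) <- c("design_matrix", class(matrix()))
  X
}

#' Fit a voxelwise GLM by ordinary least squares
#'
#' @param series A `bold_series`.
#' @param X A design matrix (volumes x regressors).
#' @return A list of class `glm_fit`: `beta` (regressor x voxel),
#'   `sigma2` (residual variance per voxel), `dof`, `XtXinv`, `dims`,
#'   `colnames`, `mask`.
#' @export
fit_glm <- function(series, X) {
  stopifnot(inherits(series, "bold_series"))
  d <- dim(series$data)
  if (nrow(X) != d[4])
    stop("design rows (", nrow(X), ") must match volumes (", d[4], ")")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    stop("design matrix rank deficient; collinear columns: ",
         paste(colnames(X)[-keep], collapse = ", "))
  }
  Y <- t(matrix(series$data, ncol = d[4]))
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  dof <- d[4] - ncol(X)
  sigma2 <- colSums(res^2) / dof
  structure(list(beta = beta, sigma2 = sigma2, dof = dof,
                 XtXinv = chol2inv(qr.R(qx)), dims = d[1:3],
                 colnames = colnames(X), mask = series$mask),
            class = "glm_fit")
}

#' Named contrast presets for the Go/NoGo task
#'
#' `"go_gt_nogo_plus_mandibulation"` weighs the Go stimulus windows
#' (Hit, Miss) against NoGo windows plus rest/ITI mandibulation
#' (CR, FA, mandib_rest); `"nogo_gt_go"` is the reverse stimulus-window
#' comparison; `"mandibulation_gt_rest"` isolates the rest/ITI
#' mandibulation regressor against implicit baseline.
#'
#' @param name Preset name.
#' @param columns Design column names (e.g. `colnames(X)`).
#' @return A numeric contrast vector over `columns`.
#' @export
contrast_preset <- function(name = c("go_gt_nogo_plus_mandibulation",
                                     "nogo_gt_go",
                                     "mandibulation_gt_rest"),
                            columns) {
  name <- match.arg(name)
  w <- setNames(numeric(length(columns)), columns)
  need <- switch(name,
    go_gt_nogo_plus_mandibulation =
      c(Hit = 0.5, Miss = 0.5, CR = -1/3, FA = -1/3, mandib_rest = -1/3),
    nogo_gt_go = c(CR = 0.5, FA = 0.5, Hit = -0.5, Miss = -0.5),
    mandibulation_gt_rest = c(mandib_rest = 1))
  missing <- setdiff(names(need), columns)
  if (length(missing))
    stop("contrast '", name, "' references absent design columns: ",
         paste(missing, collapse = ", "))
  w[names(need)] <- need
  w
}

#' Voxelwise z map for a contrast
#'
#' `t = c'beta / sqrt(c' (X'X)^{-1} c sigma^2)` converted to z through the
#' t-to-normal quantile map at the fit's degrees of freedom.
#' Zero-variance voxels get z = 0 and are flagged.
#'
#' @param fit A `glm_fit`.
#' @param contrast Numeric vector, length = number of regressors.
#' @return A 3D z map with attributes `dof`, `flagged`, `effect`
#'   (c'beta map).
#' @export
contrast_z <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  if (length(contrast) != nrow(fit$beta))
    stop("contrast length (", length(contrast),
         ") must equal regressor count (", nrow(fit$beta), ")")
  eff <- drop(contrast %*% fit$beta)
  cv <- drop(t(contrast) %*% fit$XtXinv %*% contrast)
  flag <- fit$sigma2 <= 0 | !is.finite(fit$sigma2)
  tmap <- numeric(length(eff))
  if (cv > 0) {
    ok <- !flag
    tmap[ok] <- eff[ok] / sqrt(cv * fit$sigma2[ok])
  }
  z <- array(t_to_z(tmap, fit$dof), dim = fit$dims)
  attr(z, "dof") <- fit$dof
  attr(z, "flagged") <- array(flag, dim = fit$dims)
  attr(z, "effect") <- array(eff, dim = fit$dims)
  z
}

# face-connected components of a logical 3D array; returns integer labels
label_clusters <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  nxt <- 0L
  coords <- arrayInd(idx, d)
  key <- function(x, y, z) (z - 1L) * d[1] * d[2] + (y - 1L) * d[1] + x
  inmask <- logical(prod(d))
  inmask[idx] <- TRUE
  for (s in seq_along(idx)) {
    v <- idx[s]
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (off in list(c(1L,0L,0L), c(-1L,0L,0L), c(0L,1L,0L),
                       c(0L,-1L,0L), c(0L,0L,1L), c(0L,0L,-1L))) {
        nb <- ci + off
        if (any(nb < 1L) || any(nb > d)) next
        nk <- key(nb[1], nb[2], nb[3])
        if (inmask[nk] && lab[nk] == 0L) {
          lab[nk] <- nxt
          queue <- c(queue, nk)
        }
      }
    }
  }
  lab
}

# sizes of supra-threshold face-connected clusters of a z map
cluster_sizes <- function(zmap, z_min) {
  lab <- label_clusters(zmap > z_min)
  if (max(lab) == 0L) return(integer(0))
  tabulate(lab[lab > 0L])
}

#' Cluster-extent thresholding with a permutation null
#'
#' Voxels with `z > z_min` are grouped into face-connected clusters; the
#' critical extent is the `(1 - alpha)` quantile of the maximum cluster
#' size under a null distribution of z maps supplied by `null_fun`
#' (sign-flipping at the group level, residual permutation at the first
#' level).  Clusters at least as large as the critical extent survive.
#'
#' @param zmap Observed 3D z map.
#' @param z_min Cluster-forming threshold (one-sided), default 3.1.
#' @param alpha Family-wise error level, default 0.05.
#' @param null_fun Function of one argument (permutation index) returning
#'   a null z map of the same shape.
#' @param n_permutations Number of null draws (>= 100 recommended;
#'   >= 500 for reporting).
#' @param seed Integer seed (governs `null_fun`'s RNG).
#' @return An object of class `contrast_result`: `zmap`, `clusters`
#'   (data frame: id, size, peak_z, peak x/y/z), `critical_extent`,
#'   `threshold` metadata.  No supra-threshold voxels yields an empty
#'   cluster table, not an error.
#' @export
cluster_threshold <- function(zmap, z_min = 3.1, alpha = 0.05, null_fun,
                              n_permutations = 1000, seed = 1) {
  stopifnot(z_min > 0, alpha > 0, alpha < 1)
  local_rng(seed)
  maxnull <- vapply(seq_len(n_permutations), function(i) {
    sz <- cluster_sizes(null_fun(i), z_min)
    if (length(sz)) max(sz) else 0L
  }, numeric(1))
  # critical extent: smallest k with P(null max cluster size >= k) <= alpha
  crit <- 1
  while (mean(maxnull >= crit) > alpha) crit <- crit + 1
  lab <- label_clusters(zmap > z_min)
  clusters <- data.frame(id = integer(0), size = integer(0),
                         peak_z = numeric(0), x = integer(0),
                         y = integer(0), z = integer(0))
  if (max(lab) > 0L) {
    keep_id <- 0L
    for (k in seq_len(max(lab))) {
      vox <- which(lab == k)
      if (length(vox) < crit) next
      keep_id <- keep_id + 1L
      pk <- vox[which.max(zmap[vox])]
      ci <- arrayInd(pk, dim(zmap))
      clusters <- rbind(clusters,
                        data.frame(id = keep_id, size = length(vox),
                                   peak_z = max(zmap[vox]),
                                   x = ci[1], y = ci[2], z = ci[3]))
    }
  }
  structure(list(zmap = zmap, clusters = clusters,
                 cluster_labels = lab, critical_extent = crit,
                 threshold = list(z_min = z_min, alpha = alpha,
                                  n_permutations = n_permutations,
                                  method = "permutation max-cluster-size")),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast_result: z > %g, cluster FWE alpha = %g (critical extent %g voxels)\n",
              x$threshold$z_min, x$threshold$alpha, x$critical_extent))
  if (nrow(x$clusters) == 0) cat("  no surviving clusters\n")
  else print(x$clusters)
  invisible(x)
}

#' Logical mask of voxels inside surviving clusters
#' @param result A `contrast_result`.
#' @return Logical 3D array.
#' @export
cluster_mask <- function(result) {
  m <- array(FALSE, dim = dim(result$zmap))
  if (nrow(result$clusters) > 0) {
    sizes <- tabulate(result$cluster_labels[result$cluster_labels > 0L])
    for (k in which(sizes >= result$critical_extent))
      m[result$cluster_labels == k] <- TRUE
  }
  m
}

#' Summary-statistics group inference with sign-flip cluster FWE
#'
#' Voxelwise one-sample t test on per-subject contrast-effect maps,
#' converted to z, then cluster-extent thresholded against a sign-flip
#' permutation null (each permutation multiplies every subject's map by a
#' random +/-1 and recomputes the max cluster size).  A deliberately
#' assumption-light replacement for a Bayesian mixed-effects group model
#' using the same decision rule (z > 3.1, cluster FWE 0.05).
#'
#' @param effect_maps List of per-subject 3D effect maps (common grid).
#' @param z_min Cluster-forming threshold.
#' @param alpha Cluster FWE level.
#' @param n_permutations Sign-flip permutations.
#' @param seed Integer seed.
#' @return A `contrast_result` for the group z map; attribute
#'   `group_zmap` flag marks voxels with zero between-subject variance
#'   (z capped at 38 there).
#' @export
group_level <- function(effect_maps, z_min = 3.1, alpha = 0.05,
                        n_permutations = 1000, seed = 1) {
  n_sub <- length(effect_maps)
  if (n_sub < 3) stop("group inference requires at least 3 subjects")
  dims <- dim(effect_maps[[1]])
  if (!all(vapply(effect_maps, function(m) identical(dim(m), dims), logical(1))))
    stop("all subject maps must share one grid")
  M <- t(sapply(effect_maps, as.numeric))      # subjects x voxels
  zcap <- 38                                   # ~ qnorm upper representable range
  tz <- function(mm) {
    mu <- colMeans(mm)
    sdv <- sqrt(colSums((mm - matrix(mu, n_sub, ncol(mm), byrow = TRUE))^2) /
                  (n_sub - 1))
    tt <- ifelse(sdv == 0, ifelse(mu == 0, 0, sign(mu) * 1e6),
                 mu / (sdv / sqrt(n_sub)))
    z <- t_to_z(pmin(pmax(tt, -1e6), 1e6), n_sub - 1)
    pmin(pmax(z, -zcap), zcap)
  }
  zobs <- array(tz(M), dim = dims)
  local_rng(seed)
  flips <- matrix(sample(c(-1, 1), n_sub * n_permutations, replace = TRUE),
                  n_permutations, n_sub)
  null_fun <- function(i) array(tz(M * flips[i, ]), dim = dims)
  res <- cluster_threshold(zobs, z_min = z_min, alpha = alpha,
                           null_fun = null_fun,
                           n_permutations = n_permutations, seed = seed + 1L)
  attr(res, "zero_variance") <- array(apply(M, 2, function(x) sd(x) == 0), dims)
  res
}

#' First-level permutation null via residual shuffling
#'
#' Builds a `null_fun` for [cluster_threshold()] at the single-run level:
#' the full model fit is removed, residual volumes are randomly
#' re-ordered in time, the fitted signal is added back, and the GLM +
#' contrast is recomputed (a Freedman-Lane style scheme under
#' exchangeability of residual volumes).
#'
#' @param series A `bold_series`.
#' @param X The design matrix used for the observed fit.
#' @param contrast Contrast vector.
#' @return A function of the permutation index returning a null z map.
#' @export
first_level_null <- function(series, X, contrast) {
  d <- dim(series$data)
  Y <- t(matrix(series$data, ncol = d[4]))
  qx <- qr(X)
  fitted <- qr.fitted(qx, Y)
  resid <- Y - fitted
  # the contrasted effect is removed from the re-added fit so the null
  # holds even when a true effect is present
  beta <- qr.coef(qx, Y)
  eff_cols <- which(contrast != 0)
  fitted_null <- fitted - X[, eff_cols, drop = FALSE] %*%
    beta[eff_cols, , drop = FALSE]
  tmpl <- series
  function(i) {
    perm <- sample.int(nrow(Y))
    Yp <- fitted_null + resid[perm, ]
    tmpl$data <- array(t(Yp), dim = d)
    contrast_z(fit_glm(tmpl, X), contrast)
  }
}
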