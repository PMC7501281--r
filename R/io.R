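#' Read a 4D BOLD series from a NIfTI-1 file
#'
#' @param path Path to a 4D NIfTI file.
#' @param tr Optional TR override (s); required if the header carries no
#'   positive time step.
#' @return A `bold_series`.
#' @export
read_bold <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4D NIfTI file, got ", length(d), "D")
  pix <- RNifti::pixdim(img)
  vox <- pix[1:3]
  tr_hdr <- if (length(pix) >= 4) pix[4] else 0
  if (is.null(tr)) {
    if (!is.finite(tr_hdr) || tr_hdr <= 0)
      stop("NIfTI header carries no TR; pass tr = explicitly")
    tr <- tr_hdr
  }
  bold_series(array(as.numeric(img), dim = d), tr = tr, voxel_size = vox)
}

#' Write a BOLD series to NIfTI-1
#' @param series A `bold_series`.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_bold <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an events table (tab-separated, BIDS-style)
#'
#' Columns `onset` and `duration` (s, run clock) and `trial_type` are
#' required; unknown columns are preserved.
#'
#' @param path Path to a TSV file.
#' @param tr,n_volumes Optional run geometry to attach.
#' @return An `event_table`.
#' @export
read_events <- function(path, tr = NULL, n_volumes = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("events file lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(df$onset < 0)
  if (length(bad)) stop("negative onset at line ", bad[1] + 1L)
  bad <- which(diff(df$onset) < 0)
  if (length(bad)) stop("onsets not sorted at line ", bad[1] + 2L)
  if (is.null(df$trial)) df$trial <- seq_len(nrow(df))
  atts <- list(tr = tr, n_volumes = n_volumes,
               total_duration = if (!is.null(tr) && !is.null(n_volumes))
                 tr * n_volumes else NULL,
               stimulus_duration = if (nrow(df)) df$duration[1] else NULL)
  do.call(as_event_table, c(list(df), atts[!vapply(atts, is.null, logical(1))]))
}

#' Write an events table as TSV
#' @param events An `event_table` (or data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a 6-column motion-parameter file
#'
#' Whitespace-delimited text, one row per volume: three rotations
#' (radians) then three translations (mm) — the convention of standard
#' realignment tools.
#'
#' @param path File path.
#' @return A `motion_trace`.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  motion_trace(m)
}

#' @rdname read_motion
#' @param motion A `motion_trace`.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(unclass(motion), digits = 8), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a two-channel piezo log (CSV)
#'
#' Columns: `time_s`, `signal`, `reference`.
#'
#' @param path File path.
#' @return A `piezo_trace`.
#' @export
read_piezo <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "signal", "reference")
  if (!all(need %in% names(df)))
    stop("piezo file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("piezo time axis must be strictly increasing")
  piezo_trace(df$signal, df$reference, fs = 1 / median(dt), t0 = df$time_s[1])
}

#' @rdname read_piezo
#' @param trace A `piezo_trace`.
#' @export
write_piezo <- function(trace, path) {
  n <- length(trace$signal)
  df <- data.frame(time_s = trace$t0 + (seq_len(n) - 1) / trace$fs,
                   signal = trace$signal, reference = trace$reference)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration (YAML key-value file)
#'
#' Sections: `paths`, `task`, `noise`, `behavior`, `analysis`.  Defaults
#' mirror the protocol's printed values (TR 4 s, high-pass 60 s, FWHM
#' 0.8 mm native, z 3.1, alpha 0.05).
#'
#' @param path File path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A list/`run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Default analysis parameters
#' @return Named list of the pipeline defaults.
#' @export
default_analysis_params <- function() {
  list(hrf = "pigeon", smooth_fwhm = 0.8, grand_mean = 10000,
       highpass_cutoff = 60, tsnr_cutoff = 100, z_threshold = 3.1,
       alpha = 0.05, n_permutations = 1000, detrend_order = 2,
       baseline_window = 2, epoch = 30, piezo_z = 3, refractory = 0.1)
}

#' Run an end-to-end pipeline
#'
#' `"simulate"` writes a full synthetic session bundle (BOLD NIfTI,
#' events TSV, motion text, piezo CSV, ground-truth YAML) into `out_dir`.
#' `"task"` runs smooth -> grand-mean scale -> high-pass (60 s) -> GLM ->
#' contrasts -> permutation cluster inference on a session (simulated
#' in-memory or read from `paths`).  `"hrf"` runs localizer -> ROI ->
#' averaged HDR -> nonlinear fit on a set of characterization runs.
#' Every run writes a provenance log (seed, parameters) to `out_dir`.
#'
#' @param pipeline One of `"simulate"`, `"task"`, `"hrf"`.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param config Optional `run_config` list overriding defaults.
#' @param bundle Optional pre-built `session_bundle` (task pipeline).
#' @param n_runs Number of characterization runs (hrf pipeline).
#' @return Invisibly, a list of result objects (pipeline dependent).
#' @export
run_pipeline <- function(pipeline = c("simulate", "task", "hrf"),
                         out_dir = tempfile("avihrf"), seed = 1,
                         config = NULL, bundle = NULL, n_runs = 5) {
  pipeline <- match.arg(pipeline)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- default_analysis_params()
  if (!is.null(config$analysis))
    pars[names(config$analysis)] <- config$analysis
  log <- list(pipeline = pipeline, seed = seed, parameters = pars,
              package_version = as.character(utils::packageVersion("avihrf")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  res <- switch(pipeline,
    simulate = {
      b <- simulate_session(seed = seed)
      write_bold(b$bold, file.path(out_dir, "bold.nii.gz"))
      write_events(b$events, file.path(out_dir, "events.tsv"))
      write_motion(b$motion, file.path(out_dir, "motion.par"))
      write_piezo(b$piezo, file.path(out_dir, "piezo.csv"))
      yaml::write_yaml(list(betas = as.list(b$truth$betas),
                            hrf = hrf_params_to_list(b$truth$hrf_params),
                            n_active = sum(b$truth$active_mask),
                            label = as.list(table(b$truth$label))),
                       file.path(out_dir, "truth.yaml"))
      list(bundle = b)
    },
    task = {
      if (is.null(bundle)) bundle <- simulate_session(seed = seed)
      analyze_task_session(bundle, pars, out_dir, seed = seed)
    },
    hrf = {
      characterize_hrf(n_runs = n_runs, pars = pars, out_dir = out_dir,
                       seed = seed)
    })
  yaml::write_yaml(log, file.path(out_dir, "provenance.yaml"))
  invisible(res)
}

# task pipeline: preprocessing, GLM, the three named contrasts, cluster
# inference; writes z maps, a cluster table and the design matrix
analyze_task_session <- function(bundle, pars = default_analysis_params(),
                                 out_dir = NULL, seed = 1,
                                 n_permutations = pars$n_permutations) {
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- bundle$events
  mandib <- detect_mandibulations(bundle$piezo, z_threshold = pars$piezo_z,
                                  refractory = pars$refractory)
  outcomes <- classify_trials(ev, mandib)
  pre <- highpass_filter(
    grand_mean_scale(gaussian_smooth(bundle$bold, pars$smooth_fwhm),
                     pars$grand_mean),
    cutoff = pars$highpass_cutoff)
  hrf <- if (identical(pars$hrf, "pigeon")) canonical_hrf("pigeon") else
    if (identical(pars$hrf, "human")) canonical_hrf("human") else pars$hrf
  X <- suppressWarnings(
    build_design_matrix(ev, outcomes$label, mandib, bundle$motion, hrf = hrf))
  fit <- fit_glm(pre, X)
  results <- list()
  for (cname in c("go_gt_nogo_plus_mandibulation", "nogo_gt_go",
                  "mandibulation_gt_rest")) {
    cv <- tryCatch(contrast_preset(cname, colnames(X)), error = function(e) NULL)
    if (is.null(cv)) next
    z <- contrast_z(fit, cv)
    nf <- first_level_null(pre, X, cv)
    results[[cname]] <- cluster_threshold(z, z_min = pars$z_threshold,
                                          alpha = pars$alpha, null_fun = nf,
                                          n_permutations = n_permutations,
                                          seed = seed)
  }
  if (!is.null(out_dir)) {
    utils::write.csv(X, file.path(out_dir, "design_matrix.csv"),
                     row.names = FALSE)
    write_events(outcomes, file.path(out_dir, "trial_outcomes.tsv"))
    allcl <- do.call(rbind, lapply(names(results), function(nm) {
      cl <- results[[nm]]$clusters
      if (nrow(cl)) cbind(contrast = nm, cl) else NULL
    }))
    if (is.null(allcl))
      allcl <- data.frame(contrast = character(0), id = integer(0),
                          size = integer(0), peak_z = numeric(0),
                          x = integer(0), y = integer(0), z = integer(0))
    utils::write.csv(allcl, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    for (nm in names(results)) {
      img <- RNifti::asNifti(results[[nm]]$zmap)
      RNifti::writeNifti(img, file.path(out_dir, paste0("zmap_", nm, ".nii.gz")))
    }
    sdt <- sdt_summary(outcomes)
    utils::write.csv(data.frame(hit_rate = sdt$hit_rate,
                                fa_rate = sdt$fa_rate,
                                d_prime = sdt$d_prime),
                     file.path(out_dir, "behavior_summary.csv"),
                     row.names = FALSE)
  }
  list(contrasts = results, outcomes = outcomes, design = X)
}

# HRF characterization pipeline on simulated runs: run 1 localizes, the
# remaining runs feed the averaged HDR and the nonlinear fit
characterize_hrf <- function(n_runs = 5, pars = default_analysis_params(),
                             out_dir = NULL, seed = 1,
                             true_params = canonical_hrf("pigeon"),
                             betas = c(red = 1.2, green = 1.2),
                             noise = noise_spec(), grid = c(16, 16, 4)) {
  runs <- lapply(seq_len(n_runs), function(r) {
    ev <- make_hrf_design(seed = seed + r)
    bold <- simulate_bold(ev, active_mask = default_active_mask(grid),
                          true_params = true_params, betas = betas,
                          noise = noise, grid = grid, seed = seed + 100L + r)
    # same spatial conditioning as the task pipeline before any GLM
    list(events = ev, bold = gaussian_smooth(bold, pars$smooth_fwhm))
  })
  z <- localizer_glm(runs[[1]]$bold, runs[[1]]$events)
  roi <- select_roi(z, pars$z_threshold)
  rest <- runs[-1]
  hdr <- extract_average_hdr(lapply(rest, `[[`, "bold"),
                             lapply(rest, `[[`, "events"), roi,
                             detrend_order = pars$detrend_order,
                             baseline_window = pars$baseline_window,
                             epoch = pars$epoch)
  fit <- fit_hrf(hdr, stim_duration = 2, seed = seed)
  if (!is.null(out_dir)) {
    report <- list(params = hrf_params_to_list(fit$params),
                   ci95 = apply(fit$ci95, 1, as.list),
                   rss = fit$rss, n_points = fit$n_points,
                   roi_voxels = sum(roi),
                   curve = list(values = hdr$values, dt = hdr$dt,
                                sem = hdr$sem))
    yaml::write_yaml(report, file.path(out_dir, "hrf_fit.yaml"))
  }
  list(fit = fit, hdr = hdr, roi = roi, localizer_z = z)
}
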