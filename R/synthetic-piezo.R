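#' Behavioral specification for the piezo simulator
#'
#' Defaults match observed awake-pigeon performance: high hit rate, low
#' false-alarm rate, Go (hit) latencies 0.9 +/- 0.4 s and FA latencies
#' 0.7 +/- 0.5 s (truncated below 0.05 s and above the response window),
#' drinking mandibulation during reward at ~3 Hz, plus sparse spontaneous
#' mandibulation during rest and ITI (needed to populate the GLM's
#' rest/ITI mandibulation regressor).
#'
#' @param hit_rate Probability of responding on an S+ trial.
#' @param fa_rate Probability of responding on an S- trial.
#' @param go_latency_mean,go_latency_sd Hit latency (s), truncated normal.
#' @param fa_latency_mean,fa_latency_sd FA latency (s), truncated normal.
#' @param reward_burst_rate Drinking burst rate during reward (Hz).
#' @param spontaneous_rate Rest/ITI spontaneous mandibulation rate (Hz).
#' @return A list of class `behavior_spec`.
#' @export
behavior_spec <- function(hit_rate = 0.9, fa_rate = 0.1,
                          go_latency_mean = 0.9, go_latency_sd = 0.4,
                          fa_latency_mean = 0.7, fa_latency_sd = 0.5,
                          reward_burst_rate = 3, spontaneous_rate = 0.02) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1,
            go_latency_mean > 0, go_latency_sd > 0,
            fa_latency_mean > 0, fa_latency_sd > 0,
            reward_burst_rate >= 0, spontaneous_rate >= 0)
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 go_latency_mean = go_latency_mean,
                 go_latency_sd = go_latency_sd,
                 fa_latency_mean = fa_latency_mean,
                 fa_latency_sd = fa_latency_sd,
                 reward_burst_rate = reward_burst_rate,
                 spontaneous_rate = spontaneous_rate),
            class = "behavior_spec")
}

#' Two-channel piezo trace container
#' @param signal Jaw-mounted sensor samples.
#' @param reference Reference sensor samples (same length).
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s), default 0.
#' @return Object of class `piezo_trace`.
#' @export
piezo_trace <- function(signal, reference, fs, t0 = 0) {
  if (length(signal) != length(reference))
    stop("signal and reference channels must have equal length")
  if (fs <= 0) stop("sampling rate must be positive")
  structure(list(signal = as.numeric(signal),
                 reference = as.numeric(reference),
                 fs = fs, t0 = t0),
            class = "piezo_trace")
}

#' @export
print.piezo_trace <- function(x, ...) {
  cat(sprintf("piezo_trace: %d samples at %g Hz (%.1f s)\n",
              length(x$signal), x$fs, length(x$signal) / x$fs))
  invisible(x)
}

# truncated-normal draw on [lo, hi] by inverse-CDF
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# 20 Hz damped oscillation, 150 ms: the mandibulation signature
mandib_burst <- function(fs, freq = 20, dur = 0.15, amplitude = 1, tau = 0.05) {
  tt <- seq(0, dur, by = 1 / fs)
  amplitude * sin(2 * pi * freq * tt) * exp(-tt / tau)
}

#' Simulate a two-channel piezo mandibulation log
#'
#' For each S+ trial a mandibulation burst is emitted with probability
#' `hit_rate` at a truncated-normal latency inside the stimulus window;
#' S- trials likewise with probability `fa_rate`.  Rewarded (hit) trials
#' carry Poisson drinking bursts during the reward period, and sparse
#' spontaneous bursts occur during rest/ITI.  Bursts (20 Hz damped
#' oscillations, 150 ms) appear only on the signal channel; both channels
#' carry low-amplitude Gaussian noise and occasional common-mode
#' gradient-switching artifacts appear on both (cancelled by the
#' differential detector).
#'
#' @param events An `event_table` from [make_discrimination_design()].
#' @param spec A [behavior_spec()].
#' @param sampling_rate Sampling rate (Hz, >= 50). Default 1000.
#' @param seed Integer seed.
#' @param noise_sd Baseline channel noise SD (burst amplitude is 1).
#' @return A `piezo_trace` with attribute `truth`: list with
#'   `mandib_times` (all true burst onsets, s), `trial_response_time`
#'   (per-trial first in-window response, NA if none), and `label`
#'   (Hit/Miss/CR/FA per trial).
#' @export
simulate_piezo <- function(events, spec = behavior_spec(),
                           sampling_rate = 1000, seed = 1,
                           noise_sd = 0.03) {
  if (sampling_rate < 50) stop("sampling_rate must be >= 50 Hz")
  stopifnot(inherits(spec, "behavior_spec"))
  local_rng(seed)
  total <- attr(events, "total_duration")
  if (is.null(total)) total <- max(events$onset + events$duration) + 10
  stim_dur <- attr(events, "stimulus_duration")
  if (is.null(stim_dur)) stim_dur <- events$duration[1]
  rdelay <- attr(events, "reward_delay")
  rdur <- attr(events, "reward_duration")

  n_trials <- nrow(events)
  label <- character(n_trials)
  rt <- rep(NA_real_, n_trials)
  burst_times <- numeric(0)

  for (i in seq_len(n_trials)) {
    is_go <- events$trial_type[i] %in% c("splus", "red", "green")
    p_resp <- if (events$trial_type[i] == "sminus") spec$fa_rate else spec$hit_rate
    responded <- runif(1) < p_resp
    if (responded) {
      lat <- if (events$trial_type[i] == "sminus")
        rtruncnorm1(1, spec$fa_latency_mean, spec$fa_latency_sd,
                    0.05, stim_dur - 0.05)
      else
        rtruncnorm1(1, spec$go_latency_mean, spec$go_latency_sd,
                    0.05, stim_dur - 0.05)
      rt[i] <- lat
      burst_times <- c(burst_times, events$onset[i] + lat)
    }
    label[i] <- if (events$trial_type[i] == "sminus") {
      if (responded) "FA" else "CR"
    } else {
      if (responded) "Hit" else "Miss"
    }
    # drinking during reward on rewarded (hit) trials
    if (label[i] == "Hit" && !is.na(rdelay) && spec$reward_burst_rate > 0) {
      r0 <- events$onset[i] + stim_dur + rdelay
      nb <- rpois(1, spec$reward_burst_rate * rdur)
      if (nb > 0) burst_times <- c(burst_times, sort(runif(nb, r0, r0 + rdur)))
    }
  }

  # spontaneous rest/ITI bursts: Poisson over the run, rejected inside
  # trial + post-reward epochs
  if (spec$spontaneous_rate > 0) {
    ns <- rpois(1, spec$spontaneous_rate * total)
    cand <- sort(runif(ns, 0, total))
    guard <- if (is.na(rdelay)) stim_dur + 5 else
      stim_dur + rdelay + rdur + max(attr(events, "post_reward_go"),
                                     attr(events, "post_reward_nogo"))
    keep <- vapply(cand, function(tt)
      !any(tt >= events$onset & tt < events$onset + guard), logical(1))
    burst_times <- c(burst_times, cand[keep])
  }
  burst_times <- sort(burst_times)

  n <- ceiling(total * sampling_rate)
  signal <- rnorm(n, sd = noise_sd)
  reference <- rnorm(n, sd = noise_sd)
  burst <- mandib_burst(sampling_rate)
  for (bt in burst_times) {
    i0 <- floor(bt * sampling_rate) + 1L
    idx <- i0:min(n, i0 + length(burst) - 1L)
    signal[idx] <- signal[idx] + burst[seq_along(idx)]
  }
  # common-mode artifacts (gradient switching) on both channels
  n_art <- rpois(1, total / 120)
  if (n_art > 0) {
    art <- mandib_burst(sampling_rate, freq = 35, dur = 0.08, amplitude = 0.8)
    for (at in runif(n_art, 0, total - 1)) {
      i0 <- floor(at * sampling_rate) + 1L
      idx <- i0:min(n, i0 + length(art) - 1L)
      signal[idx] <- signal[idx] + art[seq_along(idx)]
      reference[idx] <- reference[idx] + art[seq_along(idx)]
    }
  }
  out <- piezo_trace(signal, reference, fs = sampling_rate)
  attr(out, "truth") <- list(mandib_times = burst_times,
                             trial_response_time = rt, label = label)
  out
}

#' Simulate a complete experimental session bundle
#'
#' Chains the design, BOLD, motion and piezo generators with a shared
#' ground-truth record, giving every downstream analysis stage a fully
#' synthetic but statistically faithful input.
#'
#' @param task A [task_spec()].
#' @param noise A [noise_spec()].
#' @param behavior A [behavior_spec()].
#' @param betas Named peak-percent-signal-change effects per condition.
#' @param true_params Generating `hrf_params`.
#' @param grid Simulation grid shape.
#' @param seed Integer seed (sub-seeds are derived per component).
#' @param piezo_rate Piezo sampling rate (Hz).
#' @return A list of class `session_bundle` with components `events`,
#'   `bold`, `motion`, `piezo`, `truth`.
#' @export
simulate_session <- function(task = task_spec(), noise = noise_spec(),
                             behavior = behavior_spec(),
                             betas = c(splus = 1.2, sminus = 0.4),
                             true_params = canonical_hrf("pigeon"),
                             grid = c(16, 16, 4), seed = 1,
                             piezo_rate = 250) {
  seed <- as.integer(seed)
  events <- make_discrimination_design(task, seed = seed)
  active <- default_active_mask(grid)
  bold <- simulate_bold(events, active_mask = active,
                        true_params = true_params, betas = betas,
                        noise = noise, grid = grid, seed = seed + 1L)
  motion <- simulate_motion(attr(events, "n_volumes"), seed = seed + 2L)
  piezo <- simulate_piezo(events, behavior, sampling_rate = piezo_rate,
                          seed = seed + 3L)
  truth <- c(attr(piezo, "truth"),
             list(active_mask = active, betas = betas,
                  hrf_params = true_params, seed = seed))
  structure(list(events = events, bold = bold, motion = motion,
                 piezo = piezo, truth = truth),
            class = "session_bundle")
}
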