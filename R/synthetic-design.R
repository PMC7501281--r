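#' Task specification for the Go/NoGo colour discrimination protocol
#'
#' Defaults reproduce the scanning protocol: two sessions of 72 trials
#' flanked by three 10-min resting-state blocks, TR = 4 s, four
#' equiprobable stimulus conditions (S+/S- at low/high light intensity),
#' 2 s stimulus, 0.8 s delay, 1 s reward slot, inter-trial intervals
#' jittered over 12.2-20.2 s.  With these values a run lasts exactly
#' 78 min = 1170 volumes.
#'
#' @param n_trials_per_session Trials per session (divisible by 4).
#' @param n_sessions Number of task sessions.
#' @param stimulus_duration Stimulus (Go/NoGo window) duration, s.
#' @param reward_delay Delay between stimulus offset and reward onset, s.
#' @param reward_duration Reward (water delivery) duration, s.
#' @param post_reward_go Post-reward window after reward offset (Go), s.
#' @param post_reward_nogo Post-stimulus window after NoGo offset, s.
#' @param iti_range Inter-trial interval range, s (min < max).
#' @param rest_block_duration Resting-state block duration, s.
#' @param tr Repetition time, s.
#' @return A list of class `task_spec`.
#' @export
task_spec <- function(n_trials_per_session = 72, n_sessions = 2,
                      stimulus_duration = 2, reward_delay = 0.8,
                      reward_duration = 1, post_reward_go = 4,
                      post_reward_nogo = 5, iti_range = c(12.2, 20.2),
                      rest_block_duration = 600, tr = 4) {
  stopifnot(n_trials_per_session > 0, n_sessions > 0,
            stimulus_duration > 0, reward_delay > 0, reward_duration > 0,
            post_reward_go > 0, post_reward_nogo > 0,
            length(iti_range) == 2, iti_range[1] < iti_range[2],
            rest_block_duration > 0, tr > 0)
  structure(list(n_trials_per_session = as.integer(n_trials_per_session),
                 n_sessions = as.integer(n_sessions),
                 stimulus_duration = stimulus_duration,
                 reward_delay = reward_delay,
                 reward_duration = reward_duration,
                 post_reward_go = post_reward_go,
                 post_reward_nogo = post_reward_nogo,
                 iti_range = iti_range,
                 rest_block_duration = rest_block_duration,
                 tr = tr),
            class = "task_spec")
}

.trial_conditions <- c("splus_low", "splus_high", "sminus_low", "sminus_high")

#' Generate a Go/NoGo discrimination session design
#'
#' Trial order is a pseudo-random equiprobable permutation of the four
#' stimulus conditions.  Inter-trial intervals are a balanced permutation
#' of an evenly spaced grid over `iti_range` (mean exactly the midpoint,
#' 16.2 s by default), so total run duration — and hence volume count — is
#' deterministic; i.i.d. jitter could not reproduce a fixed-length run.
#' Layout: rest, session 1, rest, session 2, ..., rest.
#'
#' @param spec A [task_spec()].
#' @param seed Integer seed; the design is a pure function of
#'   `(spec, seed)`.
#' @return An `event_table`: data frame with columns `onset`, `duration`,
#'   `trial_type` (`"splus"`/`"sminus"`), `intensity` (`"low"`/`"high"`),
#'   `session`, `trial`; attributes `tr`, `n_volumes`, `total_duration`,
#'   `stimulus_duration`, `reward_delay`, `reward_duration`,
#'   `post_reward_go`, `post_reward_nogo`, `rest_blocks`.
#' @export
#' @examples
#' d <- make_discrimination_design(task_spec(), seed = 1)
#' attr(d, "n_volumes")  # 1170
make_discrimination_design <- function(spec = task_spec(), seed = 1) {
  stopifnot(inherits(spec, "task_spec"))
  n <- spec$n_trials_per_session
  if (n %% length(.trial_conditions) != 0)
    stop("n_trials_per_session must be divisible by ",
         length(.trial_conditions), " (equiprobable conditions)")
  rng <- local_rng(seed)
  trial_len <- spec$stimulus_duration + spec$reward_delay + spec$reward_duration

  rows <- list()
  t_cursor <- spec$rest_block_duration
  rest_blocks <- data.frame(onset = 0, duration = spec$rest_block_duration)
  trial_id <- 0L
  for (s in seq_len(spec$n_sessions)) {
    cond <- sample(rep(.trial_conditions, n / length(.trial_conditions)))
    itis <- sample(seq(spec$iti_range[1], spec$iti_range[2], length.out = n))
    onset <- numeric(n)
    for (i in seq_len(n)) {
      onset[i] <- t_cursor
      t_cursor <- t_cursor + trial_len + itis[i]
    }
    rows[[s]] <- data.frame(
      onset = onset,
      duration = spec$stimulus_duration,
      trial_type = sub("_(low|high)$", "", cond),
      intensity = sub("^.*_", "", cond),
      session = s,
      trial = trial_id + seq_len(n))
    trial_id <- trial_id + n
    rest_blocks <- rbind(rest_blocks,
                         data.frame(onset = t_cursor,
                                    duration = spec$rest_block_duration))
    t_cursor <- t_cursor + spec$rest_block_duration
  }
  ev <- do.call(rbind, rows)
  total <- t_cursor
  n_vol <- total / spec$tr
  if (abs(n_vol - round(n_vol)) > 1e-9)
    warning("total duration ", total, " s is not a whole number of volumes")
  as_event_table(ev, tr = spec$tr, n_volumes = as.integer(round(n_vol)),
                 total_duration = total,
                 stimulus_duration = spec$stimulus_duration,
                 reward_delay = spec$reward_delay,
                 reward_duration = spec$reward_duration,
                 post_reward_go = spec$post_reward_go,
                 post_reward_nogo = spec$post_reward_nogo,
                 rest_blocks = rest_blocks)
}

#' Generate an HRF-characterization run design
#'
#' Fixed-length trials (2 s colour stimulus + 28 s darkness by default) in
#' pseudo-random red/green order, balanced 15 per colour, with pre- and
#' post-stimulation volume padding.  Defaults reproduce the 490-volume
#' TR = 2 s characterization run.
#'
#' @param n_trials Number of trials (even; half red, half green).
#' @param stim_duration Stimulus duration, s.
#' @param rest_after Darkness after each stimulus, s.
#' @param tr Repetition time, s.
#' @param n_pre_volumes Volumes recorded before the first trial.
#' @param n_post_volumes Volumes recorded after the last trial.
#' @param seed Integer seed.
#' @return An `event_table` with `trial_type` in `"red"`/`"green"`.
#' @export
#' @examples
#' d <- make_hrf_design(seed = 1)
#' attr(d, "n_volumes")  # 490
make_hrf_design <- function(n_trials = 30, stim_duration = 2,
                            rest_after = 28, tr = 2,
                            n_pre_volumes = 30, n_post_volumes = 10,
                            seed = 1) {
  stopifnot(n_trials > 0, stim_duration > 0, rest_after > 0, tr > 0,
            n_pre_volumes > 0, n_post_volumes > 0)
  if (n_trials %% 2 != 0) stop("n_trials must be even (balanced colours)")
  rng <- local_rng(seed)
  colours <- sample(rep(c("red", "green"), n_trials / 2))
  trial_len <- stim_duration + rest_after
  onset <- n_pre_volumes * tr + (seq_len(n_trials) - 1) * trial_len
  total <- n_pre_volumes * tr + n_trials * trial_len + n_post_volumes * tr
  ev <- data.frame(onset = onset, duration = stim_duration,
                   trial_type = colours, intensity = "high",
                   session = 1L, trial = seq_len(n_trials))
  as_event_table(ev, tr = tr, n_volumes = as.integer(round(total / tr)),
                 total_duration = total, stimulus_duration = stim_duration,
                 reward_delay = NA_real_, reward_duration = NA_real_,
                 post_reward_go = NA_real_, post_reward_nogo = NA_real_,
                 rest_blocks = data.frame(onset = numeric(0),
                                          duration = numeric(0)))
}

as_event_table <- function(df, ...) {
  atts <- list(...)
  for (nm in names(atts)) attr(df, nm) <- atts[[nm]]
  class(df) <- c("event_table", "data.frame")
  df
}

# Seed handling: every generator is a pure function of (spec, seed) and
# leaves the caller's RNG state untouched.
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed))
    withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
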