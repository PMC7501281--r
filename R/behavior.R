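#' Detect mandibulation events from a two-channel piezo trace
#'
#' The differential signal (signal - reference) cancels common-mode
#' scanner artifacts.  A causal 50 ms RMS envelope integrates over the
#' oscillation cycles of a burst; its logarithm (whose baseline
#' distribution is close to Gaussian, unlike the heavy-tailed envelope
#' itself) is standardized robustly — median removed, scaled by
#' 1.4826 * MAD — and events are registered at upward crossings of
#' `z_threshold`; crossings closer than `refractory` are merged into one
#' event.
#'
#' Exceedances shorter than `min_duration` (noise blips, unlike the
#' >= 100 ms envelope of a real burst) are discarded.
#'
#' @param trace A `piezo_trace` (sampling rate >= 50 Hz).
#' @param z_threshold Robust z threshold on the log envelope. Default 3.
#' @param refractory Minimum separation between events (s). Default 0.1.
#' @param envelope_window RMS envelope window (s). Default 0.05.
#' @param min_duration Minimum time the envelope must stay above
#'   threshold (s). Default 0.02.
#' @return Numeric vector of event times (s); empty for a flat trace.
#' @export
detect_mandibulations <- function(trace, z_threshold = 3, refractory = 0.1,
                                  envelope_window = 0.05,
                                  min_duration = 0.02) {
  stopifnot(inherits(trace, "piezo_trace"))
  if (trace$fs < 50) stop("sampling rate must be >= 50 Hz")
  d <- trace$signal - trace$reference
  win <- max(2L, round(envelope_window * trace$fs))
  ma <- as.numeric(stats::filter(d^2, rep(1 / win, win), sides = 1))
  ma[is.na(ma)] <- ma[win]
  env <- log(sqrt(pmax(ma, .Machine$double.eps)))
  md <- median(env)
  s <- mad_stat(env) * 1.4826
  if (s == 0) return(numeric(0))
  z <- (env - md) / s
  above <- z > z_threshold
  ups <- which(above & !c(FALSE, above[-length(above)]))
  if (length(ups) == 0) return(numeric(0))
  # debounce: keep only crossings whose exceedance lasts min_duration
  need <- max(1L, round(min_duration * trace$fs))
  downs <- which(!above & c(FALSE, above[-length(above)]))
  runlen <- vapply(ups, function(u) {
    nxt <- downs[downs > u]
    (if (length(nxt)) nxt[1] else length(above) + 1L) - u
  }, numeric(1))
  ups <- ups[runlen >= need]
  if (length(ups) == 0) return(numeric(0))
  # hysteresis: a new event requires the envelope to have dipped below
  # the re-arm level since the previous crossing (suppresses re-triggers
  # on the decaying tail of one burst)
  rearm <- cumsum(z < z_threshold - 1.5)
  times <- trace$t0 + (ups - 1) / trace$fs
  merged <- numeric(0)
  last_t <- -Inf
  last_i <- 0L
  for (k in seq_along(ups)) {
    dipped <- last_i == 0L || rearm[ups[k]] > rearm[last_i]
    if (times[k] - last_t > refractory && dipped) {
      merged <- c(merged, times[k])
      last_t <- times[k]
      last_i <- ups[k]
    }
  }
  merged
}

#' Classify trials into Hit / Miss / CR / FA
#'
#' A trial is responded if at least one mandibulation event falls in
#' `[onset, onset + stimulus_duration)`.  S+ trials with a response are
#' Hits, without are Misses; S- trials with a response are FAs, without
#' are CRs.  Reaction time is the first in-window event minus onset
#' (Hit/FA only).
#'
#' @param events An `event_table` (trial types `splus`/`sminus`; red and
#'   green trials are treated as S+).
#' @param mandib_times Detected mandibulation times (s).
#' @return A data frame of class `trial_outcomes`: `trial`, `type`,
#'   `label`, `rt_s`, `n_mandib`, plus `rate_per_s` (count over the
#'   stimulus window divided by its length, for convenience).
#' @export
classify_trials <- function(events, mandib_times) {
  stim_dur <- attr(events, "stimulus_duration")
  if (is.null(stim_dur)) stim_dur <- events$duration[1]
  o <- order(events$onset)
  if (any(diff(events$onset[o]) < stim_dur))
    stop("overlapping trials: stimulus windows intersect")
  mandib_times <- sort(mandib_times)
  out <- data.frame(trial = events$trial, type = events$trial_type,
                    label = NA_character_, rt_s = NA_real_,
                    n_mandib = 0L)
  for (i in seq_len(nrow(events))) {
    w <- mandib_times[mandib_times >= events$onset[i] &
                        mandib_times < events$onset[i] + stim_dur]
    responded <- length(w) > 0
    is_nogo <- events$trial_type[i] == "sminus"
    out$label[i] <- if (is_nogo) {
      if (responded) "FA" else "CR"
    } else {
      if (responded) "Hit" else "Miss"
    }
    out$n_mandib[i] <- length(w)
    if (responded && out$label[i] %in% c("Hit", "FA"))
      out$rt_s[i] <- w[1] - events$onset[i]
  }
  out$rate_per_s <- out$n_mandib / stim_dur
  class(out) <- c("trial_outcomes", "data.frame")
  attr(out, "stimulus_duration") <- stim_dur
  out
}

#' Signal-detection-theory session summary
#'
#' Hit rate = Hits / (Hits + Misses), FA rate = FAs / (FAs + CRs),
#' sensitivity `d' = qnorm(hit) - qnorm(fa)`.  Extreme rates (0 or 1)
#' would give infinite d'; the log-linear correction (add 0.5 to every
#' cell, 1 to each denominator) is applied before the transform when
#' `correction = "loglinear"` (the default applies it always, keeping
#' estimates comparable across sessions).
#'
#' @param outcomes A `trial_outcomes` data frame (or any data frame with
#'   a `label` column).
#' @param correction `"loglinear"` (always applied) or `"none"`.
#' @return A list of class `sdt_summary`: `hit_rate`, `fa_rate`,
#'   `d_prime`, `counts` (named Hit/Miss/CR/FA).
#' @export
#' @examples
#' oc <- data.frame(label = c(rep("Hit", 30), rep("Miss", 6),
#'                            rep("CR", 32), rep("FA", 4)))
#' sdt_summary(oc)
sdt_summary <- function(outcomes, correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  counts <- sapply(c("Hit", "Miss", "CR", "FA"),
                   function(l) sum(outcomes$label == l))
  n_go <- counts[["Hit"]] + counts[["Miss"]]
  n_nogo <- counts[["CR"]] + counts[["FA"]]
  if (n_go < 1 || n_nogo < 1)
    stop("need at least one S+ and one S- trial")
  hit_rate <- counts[["Hit"]] / n_go
  fa_rate <- counts[["FA"]] / n_nogo
  if (correction == "loglinear") {
    h <- (counts[["Hit"]] + 0.5) / (n_go + 1)
    f <- (counts[["FA"]] + 0.5) / (n_nogo + 1)
  } else {
    h <- hit_rate
    f <- fa_rate
  }
  structure(list(hit_rate = unname(hit_rate), fa_rate = unname(fa_rate),
                 d_prime = qnorm(h) - qnorm(f),
                 counts = counts),
            class = "sdt_summary")
}

#' @export
print.sdt_summary <- function(x, ...) {
  cat(sprintf("SDT summary: hit rate %.3f, FA rate %.3f, d' = %.3f\n",
              x$hit_rate, x$fa_rate, x$d_prime))
  cat("  counts:", paste(names(x$counts), x$counts, collapse = ", "), "\n")
  invisible(x)
}

#' ROC-space coordinates of a session
#'
#' @param summary An `sdt_summary`.
#' @return A list `(fa, hit, above_diagonal)` for plotting/aggregation.
#' @export
roc_point <- function(summary) {
  stopifnot(inherits(summary, "sdt_summary"))
  list(fa = summary$fa_rate, hit = summary$hit_rate,
       above_diagonal = summary$hit_rate > summary$fa_rate)
}

#' Peri-stimulus histogram of mandibulation events
#'
#' Counts of events per time bin relative to stimulus onset, split by
#' S+ and S- trials.
#'
#' @param events An `event_table`.
#' @param mandib_times Event times (s).
#' @param bin Bin width (s, > 0). Default 0.2.
#' @param window Peri-stimulus window `c(from, to)` (s). Default
#'   `c(-2, 10)`.
#' @return A data frame: `bin_start`, `bin_end`, `splus`, `sminus`.
#' @export
peristimulus_histogram <- function(events, mandib_times, bin = 0.2,
                                   window = c(-2, 10)) {
  if (bin <= 0) stop("bin must be > 0")
  edges <- seq(window[1], window[2], by = bin)
  if (max(edges) < window[2]) edges <- c(edges, max(edges) + bin)
  counts <- matrix(0L, length(edges) - 1L, 2,
                   dimnames = list(NULL, c("splus", "sminus")))
  for (i in seq_len(nrow(events))) {
    rel <- mandib_times - events$onset[i]
    rel <- rel[rel >= window[1] & rel < max(edges)]
    if (!length(rel)) next
    grp <- if (events$trial_type[i] == "sminus") "sminus" else "splus"
    h <- hist(rel, breaks = edges, plot = FALSE)$counts
    counts[, grp] <- counts[, grp] + h
  }
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             splus = counts[, "splus"], sminus = counts[, "sminus"])
}
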