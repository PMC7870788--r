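# Idealization of current traces into discrete conduction levels:
# amplitude-histogram level detection, half-amplitude threshold crossing
# with hysteresis, dwell-time statistics and empirical open probabilities.

#' Remove a slowly drifting baseline from a trace
#'
#' Fits a straight line to the lower envelope of the current (per-window
#' low quantiles, which track the closed level even when channels are open
#' part of the time) and subtracts its slope, anchored at the start of the
#' trace. A drift-free trace is returned essentially unchanged.
#'
#' @param trace a [current_trace()] (longer than 10 samples).
#' @param window_s envelope window length.
#' @param probs quantile defining the lower envelope.
#' @return The detrended `current_trace`; the removed slope (A/s) is
#'   recorded in the metadata as `baseline_drift_A_per_s`.
#' @export
baseline_correct <- function(trace, window_s = 0.1, probs = 0.1) {
  stopifnot(inherits(trace, "current_trace"), nrow(trace) > 10)
  t <- trace$time_s - trace$time_s[1]
  x <- trace$current_A
  nw <- max(4L, floor(t[length(t)] / window_s))
  bins <- cut(t, nw, labels = FALSE)
  env_t <- tapply(t, bins, mean)
  sign_flip <- stats::median(x) < 0  # track the envelope nearest zero
  env_i <- tapply(x, bins, stats::quantile,
                  probs = if (sign_flip) 1 - probs else probs,
                  names = FALSE)
  # Theil-Sen slope: immune to windows where no closed-state samples occur
  ij <- utils::combn(length(env_t), 2)
  slope <- stats::median((env_i[ij[2, ]] - env_i[ij[1, ]]) /
                           (env_t[ij[2, ]] - env_t[ij[1, ]]))
  trace$current_A <- x - slope * t
  attr(trace, "metadata")$baseline_drift_A_per_s <- slope
  trace
}

# density peaks with a prominence requirement, used as candidate levels;
# the bandwidth is floored at a fraction of the amplitude range so that
# near-noiseless quantized traces keep well-resolved point masses
find_level_peaks <- function(x, min_prom = 0.05) {
  rng <- diff(range(x))
  if (rng == 0) return(x[1])
  bw <- max(stats::bw.nrd0(x), rng / 100)
  d <- stats::density(x, bw = bw, n = 1024)
  y <- c(0, d$y / max(d$y), 0)  # pad so endpoint maxima count
  k <- 2:(length(y) - 1)
  pk <- k[y[k] > y[k - 1] & y[k] >= y[k + 1] & y[k] > min_prom] - 1L
  if (length(pk) == 0) return(numeric(0))
  # merge peaks closer than one bandwidth
  locs <- d$x[pk]
  hts <- y[pk]
  keep <- rep(TRUE, length(locs))
  for (j in seq_along(locs)) {
    if (!keep[j]) next
    close <- which(abs(locs - locs[j]) < 2 * d$bw & seq_along(locs) != j)
    close <- close[keep[close]]
    if (length(close)) keep[close[hts[close] <= hts[j]]] <- FALSE
  }
  sort(locs[keep])
}

# half-amplitude threshold crossing with hysteresis over (possibly) many
# equally spaced levels; u is the current in units of one step above
# baseline (signed so that open excursions are positive)
threshold_levels <- function(u, enter = 0.5, exit = 0.35) {
  n <- length(u)
  lev <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (u[i] > cur + enter) {
      cur <- cur + 1L
    } else if (u[i] < cur - 1L + exit) {
      cur <- max(cur - 1L, 0L)
    }
    lev[i] <- cur
  }
  lev
}

# merge runs shorter than min_len samples into their predecessor's level
merge_short_runs <- function(lev, min_len) {
  repeat {
    r <- rle(lev)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_len)
    short <- short[short > 1]
    if (length(short) == 0) break
    r$values[short[1]] <- r$values[short[1] - 1]
    lev <- inverse.rle(r)
  }
  lev
}

#' Idealize a current trace into discrete conduction levels
#'
#' Detects the quantized conduction levels of a (baseline-corrected)
#' trace: candidate levels come from the peaks of the amplitude
#' distribution; the open-step size is the modal nearest-level spacing
#' (identical pores produce equally spaced levels); samples are then
#' assigned to levels by half-amplitude threshold crossing with hysteresis
#' (enter a level at 0.5 steps above it, leave at 0.35) and events shorter
#' than `min_event_s` are merged away. A unimodal amplitude distribution
#' returns an empty event list with one level -- no channels -- rather
#' than an error. When the trace has a holding segment, only the step
#' segment (after a short settling time) is idealized.
#'
#' @param trace a [current_trace()], ideally after [baseline_correct()].
#' @param min_event_s shortest retained event (default 2 ms, about four
#'   samples at a 2 kHz recording bandwidth, suppressing filter-limited
#'   glitches).
#' @param enter,exit hysteresis thresholds in units of one step.
#' @param settle_s step-onset settling time excluded from idealization.
#' @return An object of class `"event_list"`: `events` (start_s, end_s,
#'   level_index, amplitude_A relative to baseline), `baseline_A`,
#'   `step_amplitude_A` (signed modal step), `n_levels`, `duration_s`,
#'   `mean_level` (time-averaged level index) and the source voltage.
#' @export
idealize <- function(trace, min_event_s = 0.002, enter = 0.5, exit = 0.35,
                     settle_s = 0.02) {
  stopifnot(inherits(trace, "current_trace"))
  md <- attr(trace, "metadata")
  rel <- trace$time_s - trace$time_s[1]
  onset <- if (!is.null(md$pre_step_s)) md$pre_step_s else 0
  idx <- rel >= onset + settle_s
  t <- rel[idx] - (onset + settle_s)
  x <- trace$current_A[idx]
  fs <- 1 / diff(trace$time_s[1:2])
  duration <- length(x) / fs
  voltage <- if (!is.null(md$level_V)) md$level_V else
    stats::median(trace$voltage_V[idx])

  empty <- function(baseline, nlev) {
    structure(list(events = data.frame(start_s = numeric(0),
                                       end_s = numeric(0),
                                       level_index = integer(0),
                                       amplitude_A = numeric(0)),
                   baseline_A = baseline, step_amplitude_A = NA_real_,
                   n_levels = nlev, duration_s = duration,
                   mean_level = 0, open_time_s = 0,
                   voltage_V = voltage,
                   n_pores = md$n_pores,
                   sample_rate_Hz = fs),
              class = "event_list")
  }
  peaks <- find_level_peaks(x)
  if (length(peaks) <= 1)
    return(empty(if (length(peaks)) peaks else mean(x), 1L))

  # closed level: the peak nearest zero along the driving direction
  open_sign <- if (stats::median(x) >= 0) 1 else -1
  baseline <- if (open_sign > 0) peaks[1] else peaks[length(peaks)]
  step <- open_sign * stats::median(diff(peaks))

  u <- (x - baseline) / step
  lev <- threshold_levels(u, enter, exit)
  lev <- merge_short_runs(lev, max(1L, round(min_event_s * fs)))

  r <- rle(lev)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  open_runs <- which(r$values >= 1L)
  events <- data.frame(
    start_s = t[starts[open_runs]],
    end_s = t[ends[open_runs]] + 1 / fs,
    level_index = r$values[open_runs],
    amplitude_A = r$values[open_runs] * step)
  structure(list(events = events, baseline_A = baseline,
                 step_amplitude_A = step,
                 n_levels = length(peaks), duration_s = duration,
                 mean_level = mean(lev),
                 open_time_s = sum(lev >= 1L) / fs,
                 voltage_V = voltage,
                 n_pores = md$n_pores,
                 sample_rate_Hz = fs),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("Event list: %d events, %d level(s)", nrow(x$events),
              x$n_levels))
  if (!is.na(x$step_amplitude_A))
    cat(sprintf(", step %.3g pA", 1e12 * x$step_amplitude_A))
  cat(sprintf(", %.3g s at %.0f mV\n", x$duration_s, 1e3 * x$voltage_V))
  invisible(x)
}

#' Dwell-time statistics of an event list
#'
#' Open dwells are the durations of contiguous excursions above the
#' baseline; closed dwells the gaps between them. For each the mean,
#' count, and the rate of a maximum-likelihood exponential fit (the
#' reciprocal mean) are reported.
#'
#' @param events an [idealize()] result.
#' @return A list with components `open` and `closed`, each holding `n`,
#'   `mean_s`, `rate_per_s`, and the dwell vector `dwells_s`.
#' @export
dwell_time_stats <- function(events) {
  stopifnot(inherits(events, "event_list"))
  ev <- events$events
  if (nrow(ev) == 0) {
    z <- list(n = 0L, mean_s = NA_real_, rate_per_s = NA_real_,
              dwells_s = numeric(0))
    return(list(open = z, closed = z))
  }
  # merge contiguous events (multi-level excursions) into open periods
  open_start <- ev$start_s[c(TRUE, ev$start_s[-1] - ev$end_s[-nrow(ev)] >
                               1e-12)]
  open_end <- ev$end_s[c(ev$start_s[-1] - ev$end_s[-nrow(ev)] > 1e-12,
                         TRUE)]
  open_dw <- open_end - open_start
  closed_dw <- open_start[-1] - open_end[-length(open_end)]
  mk <- function(d) list(n = length(d),
                         mean_s = if (length(d)) mean(d) else NA_real_,
                         rate_per_s = if (length(d)) 1 / mean(d)
                         else NA_real_,
                         dwells_s = d)
  list(open = mk(open_dw), closed = mk(closed_dw))
}

#' Empirical open probability across voltages
#'
#' Tabulates, for a set of idealized traces at different voltages, the
#' fraction of time the membrane spends at one or more open levels
#' (`p_any_open`) and -- when the pore count is known -- the
#' time-averaged open fraction per pore (`p_per_pore`, the time-averaged
#' level index divided by the pore count), which is the quantity directly
#' comparable with [open_probability()].
#'
#' @param eventlists list of [idealize()] results at two or more voltages.
#' @param n_pores pore count used for the per-pore normalization;
#'   defaults to each event list's recorded value.
#' @return A data.frame with one row per voltage.
#' @export
empirical_open_probability <- function(eventlists, n_pores = NULL) {
  stopifnot(is.list(eventlists), length(eventlists) >= 2)
  rows <- lapply(eventlists, function(el) {
    stopifnot(inherits(el, "event_list"))
    np <- if (!is.null(n_pores)) n_pores else el$n_pores
    data.frame(voltage_V = el$voltage_V,
               p_any_open = el$open_time_s / el$duration_s,
               p_per_pore = if (!is.null(np) && np > 0)
                 el$mean_level / np else NA_real_,
               n_events = nrow(el$events))
  })
  do.call(rbind, rows)
}
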