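# Stochastic voltage-clamp trace simulator: step protocol, two-state Markov
# pore gating, biexponential jump transients, white noise and causal
# low-pass filtering. Patch mode keeps the polarization offset V0; BLM mode
# forces V0 = 0 (flat bilayer).

#' Voltage-step protocol
#'
#' Builds the arithmetic sequence of command voltages for an I-V series.
#' The default protocol steps from +200 to -200 mV in -25 mV increments
#' (17 levels), holding each level for 3.1 s after a 50 ms holding segment,
#' sampled at 10 kHz.
#'
#' @param start_V,stop_V first and last step voltage in volts.
#' @param step_V increment in volts; `stop_V - start_V` must be an integer
#'   multiple of it (a single level is allowed when `start_V == stop_V`).
#' @param step_s duration of each voltage step in seconds.
#' @param pre_step_s holding-segment duration preceding each step; the jump
#'   therefore occurs at `t = pre_step_s` within each trace.
#' @param sample_rate_Hz sampling frequency.
#' @param holding_V holding voltage between steps.
#' @return An object of class `"voltage_protocol"` with fields `levels_V`,
#'   `n_levels`, and `total_stepped_s`.
#' @examples
#' p <- build_protocol()
#' p$n_levels          # 17
#' p$total_stepped_s   # 52.7
#' @export
build_protocol <- function(start_V = 0.2, stop_V = -0.2, step_V = -0.025,
                           step_s = 3.1, pre_step_s = 0.05,
                           sample_rate_Hz = 10000, holding_V = 0) {
  stopifnot(step_s > 0, pre_step_s > 0, sample_rate_Hz > 0)
  if (start_V == stop_V) {
    levels <- start_V
  } else {
    if (step_V == 0) stop("step_V must be non-zero")
    n_steps <- (stop_V - start_V) / step_V
    if (n_steps < 0 || abs(n_steps - round(n_steps)) > 1e-9)
      stop("stop_V - start_V must be a non-negative integer multiple of step_V")
    levels <- start_V + step_V * seq(0, round(n_steps))
  }
  structure(list(levels_V = levels,
                 n_levels = length(levels),
                 holding_V = holding_V,
                 pre_step_s = pre_step_s,
                 step_s = step_s,
                 sample_rate_Hz = sample_rate_Hz,
                 total_stepped_s = length(levels) * step_s),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("Voltage protocol: %d levels (%g to %g mV), %g s per step (+%g ms holding), %g kHz\n",
              x$n_levels, 1e3 * x$levels_V[1], 1e3 * x$levels_V[x$n_levels],
              x$step_s, 1e3 * x$pre_step_s, x$sample_rate_Hz / 1e3))
  cat(sprintf("  total stepped duration %.1f s\n", x$total_stepped_s))
  invisible(x)
}

#' Two-state gating kinetics
#'
#' The closing rate is voltage-independent, `k_close = 1/mean_open_lifetime`
#' (single-pore conductance and open lifetime do not depend on voltage);
#' all voltage dependence sits in the opening rate,
#' `k_open(V) = k_close * K(V)`, so that the stationary occupancy is exactly
#' the equilibrium open probability `P_open(V) = K/(1+K)`.
#'
#' @param mean_open_lifetime_s mean open dwell time in seconds; observed
#'   lipid-channel lifetimes are of order 10-100 ms (default 30 ms).
#' @return An object of class `"gating_kinetics"`.
#' @export
gating_kinetics <- function(mean_open_lifetime_s = 0.03) {
  stopifnot(mean_open_lifetime_s > 0)
  structure(list(mean_open_lifetime_s = mean_open_lifetime_s,
                 k_close_per_s = 1 / mean_open_lifetime_s),
            class = "gating_kinetics")
}

#' Post-jump transient parameters
#'
#' Amplitudes and time constants of the biexponential current transient
#' that follows each voltage jump: a fast capacitor-charging component
#' (tau0) and a slow membrane-relaxation component (taum). Amplitudes
#' scale linearly with the jump size `dV`: `A0 = a0_per_V * dV`,
#' `Am = am_per_V * dV`. Alternatively a [transient_decomposition()] can be
#' supplied, from which the amplitudes of each jump are computed exactly.
#'
#' @param tau_fast_s fast time constant tau0 (default 258 us, the scale set
#'   by the recording filter).
#' @param tau_slow_s slow time constant taum (default 1.74 ms, the membrane
#'   relaxation scale); must exceed `tau_fast_s`.
#' @param a0_per_V fast amplitude per volt of jump (default `Cm/tau0` with
#'   Cm = 100 pF, i.e. ideal-capacitor charging).
#' @param am_per_V slow amplitude per volt of jump.
#' @param decomposition optional [transient_decomposition()]; when given it
#'   overrides the per-volt amplitudes.
#' @return An object of class `"transient_params"`.
#' @export
transient_params <- function(tau_fast_s = 258e-6, tau_slow_s = 1.74e-3,
                             a0_per_V = 100e-12 / 258e-6, am_per_V = 1e-9,
                             decomposition = NULL) {
  stopifnot(tau_fast_s > 0, tau_slow_s > tau_fast_s)
  if (!is.null(decomposition))
    stopifnot(inherits(decomposition, "transient_decomposition"))
  structure(list(tau_fast_s = tau_fast_s, tau_slow_s = tau_slow_s,
                 a0_per_V = a0_per_V, am_per_V = am_per_V,
                 decomposition = decomposition),
            class = "transient_params")
}

#' Measurement noise and recording filter
#'
#' White current noise added per raw sample, then a causal digital low-pass
#' (Butterworth approximation to the hardware Bessel filter, applied
#' forward only) with unit DC gain.
#'
#' @param current_noise_sd_A white-noise standard deviation per sample.
#' @param filter_cutoff_Hz low-pass cutoff; `NULL` disables filtering. Must
#'   stay below the Nyquist frequency.
#' @param filter_order filter order (poles), default 4.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(current_noise_sd_A = 2e-12, filter_cutoff_Hz = 2000,
                        filter_order = 4) {
  stopifnot(current_noise_sd_A >= 0)
  if (!is.null(filter_cutoff_Hz)) stopifnot(filter_cutoff_Hz > 0)
  structure(list(current_noise_sd_A = current_noise_sd_A,
                 filter_cutoff_Hz = filter_cutoff_Hz,
                 filter_order = filter_order),
            class = "noise_model")
}

# Exact continuous-time two-state trajectory for one pore: alternating
# exponential dwells. Returns transition times in (0, duration] and the
# initial state.
simulate_pore_dwells <- function(k_open, k_close, duration_s, p_init) {
  state <- stats::rbinom(1L, 1L, p_init)
  if (!is.finite(k_open)) {            # absorbing open limit
    return(list(state0 = 1L, times = numeric(0)))
  }
  if (k_open <= 0) {                   # never opens; may close once
    if (state == 0L) return(list(state0 = 0L, times = numeric(0)))
    t1 <- stats::rexp(1L, k_close)
    return(list(state0 = 1L,
                times = if (t1 < duration_s) t1 else numeric(0)))
  }
  times <- numeric(0)
  t <- 0
  s <- state
  repeat {
    rate <- if (s == 1L) k_close else k_open
    t <- t + stats::rexp(1L, rate)
    if (t >= duration_s) break
    times <- c(times, t)
    s <- 1L - s
  }
  list(state0 = state, times = times)
}

#' Simulate stochastic pore gating
#'
#' Continuous-time two-state Markov trajectories for `n_pores` independent
#' pores at a fixed voltage, sampled onto a regular grid. Open dwells are
#' exponential with mean `1/k_close`; closed dwells with mean
#' `1/k_open(V)`. Initial states are drawn from the equilibrium
#' distribution (optionally at a different voltage, e.g. the pre-jump
#' holding level).
#'
#' @param pe a [pore_energetics()].
#' @param gk a [gating_kinetics()].
#' @param n_pores number of independent pores (>= 0).
#' @param v voltage in volts at which the pores gate.
#' @param duration_s simulated duration.
#' @param seed optional integer seed (`set.seed` is called when non-NULL).
#' @param sample_rate_Hz grid sampling rate.
#' @param p_init initial open probability for each pore; defaults to the
#'   equilibrium `open_probability(pe, v)`.
#' @return An object of class `"gating_sim"`: list with `time_s`, `n_open`
#'   (integer open-pore count per sample), `open_fraction` (exact
#'   time-averaged open fraction per pore slot), `n_openings` (number of
#'   opening transitions), and `dwells` (completed dwell durations by
#'   state).
#' @export
simulate_gating <- function(pe, gk, n_pores, v, duration_s, seed = NULL,
                            sample_rate_Hz = 10000, p_init = NULL) {
  stopifnot(inherits(pe, "pore_energetics"), inherits(gk, "gating_kinetics"),
            n_pores >= 0, duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  k_close <- gk$k_close_per_s
  # k_open = k_close * K(v); computed in log space to survive large |dmu0|
  log_K <- -pore_free_energy(pe, v)
  k_open <- k_close * exp(log_K)
  if (is.null(p_init)) p_init <- open_probability(pe, v)

  n_samp <- max(1L, round(duration_s * sample_rate_Hz))
  time_s <- seq(0, by = 1 / sample_rate_Hz, length.out = n_samp)
  n_open <- integer(n_samp)
  open_time <- 0
  n_openings <- 0L
  dwell_open <- list(); dwell_closed <- list()

  if (n_pores > 0) {
    for (i in seq_len(n_pores)) {
      pd <- simulate_pore_dwells(k_open, k_close, duration_s, p_init)
      # state at each grid point: parity of transitions before it
      n_open <- n_open +
        ((pd$state0 + findInterval(time_s, pd$times)) %% 2L)
      # exact open time and completed dwells
      bounds <- c(0, pd$times, duration_s)
      durs <- diff(bounds)
      states <- (pd$state0 + seq_along(durs) - 1L) %% 2L
      open_time <- open_time + sum(durs[states == 1L])
      n_openings <- n_openings + sum(states == 1L & seq_along(durs) > 1L) +
        0L
      if (length(pd$times) >= 2L) {
        inner <- durs[seq(2L, length(durs) - 1L)]
        inner_states <- states[seq(2L, length(states) - 1L)]
        dwell_open[[i]] <- inner[inner_states == 1L]
        dwell_closed[[i]] <- inner[inner_states == 0L]
      }
    }
  }
  structure(list(time_s = time_s,
                 n_open = as.integer(n_open),
                 n_pores = n_pores,
                 v = v,
                 open_fraction = if (n_pores > 0)
                   open_time / (duration_s * n_pores) else 0,
                 n_openings = n_openings,
                 dwells = list(open = unlist(dwell_open),
                               closed = unlist(dwell_closed)),
                 k_open_per_s = k_open,
                 k_close_per_s = k_close),
            class = "gating_sim")
}

# biexponential transient evaluated on a time grid starting at the jump
transient_curve <- function(t, a0, am, tau0, taum) {
  a0 * exp(-t / tau0) + am * exp(-t / taum)
}

# amplitudes of the jump transient for a jump v_before -> v_after
transient_amplitudes <- function(tp, v_before, v_after) {
  dv <- v_after - v_before
  if (!is.null(tp$decomposition)) {
    td <- tp$decomposition
    a0 <- td$cap_before_F * dv / tp$tau_fast_s
    am <- (td$d_cap_F * v_after + td$d_pol_charge_C) / tp$tau_slow_s -
      td$d_g_S * v_after
    list(a0 = a0, am = am)
  } else {
    list(a0 = tp$a0_per_V * dv, am = tp$am_per_V * dv)
  }
}

apply_lowpass <- function(x, sample_rate_Hz, cutoff_Hz, order = 4) {
  if (is.null(cutoff_Hz)) return(x)
  if (cutoff_Hz >= sample_rate_Hz / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, 2 * cutoff_Hz / sample_rate_Hz, type = "low")
  as.numeric(signal::filter(bf, x))
}

#' Construct a current trace
#'
#' A sampled voltage-clamp current trace: regular time base, commanded
#' voltage per sample, measured current, plus a metadata list that fully
#' records how the trace was produced (protocol, generating parameters,
#' seed, condition labels).
#'
#' @param time_s,voltage_V,current_A equal-length numeric vectors; time must
#'   be strictly increasing with regular spacing.
#' @param metadata named list of provenance information; must contain
#'   `sample_rate_Hz`.
#' @return An object of class `"current_trace"` (a data.frame with a
#'   `metadata` attribute).
#' @export
current_trace <- function(time_s, voltage_V, current_A, metadata = list()) {
  n <- length(time_s)
  stopifnot(length(voltage_V) == n, length(current_A) == n, n > 1)
  dt <- diff(time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt))
    stop("time_s must be strictly increasing with regular spacing")
  out <- data.frame(time_s = time_s, voltage_V = voltage_V,
                    current_A = current_A)
  attr(out, "metadata") <- metadata
  class(out) <- c("current_trace", "data.frame")
  out
}

#' @export
print.current_trace <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("Current trace: %d samples, %.3f s", nrow(x),
              x$time_s[nrow(x)] - x$time_s[1]))
  if (!is.null(md$level_V)) cat(sprintf(", step to %g mV", 1e3 * md$level_V))
  cat("\n")
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$current_A * 1e12, type = "l",
                 xlab = "time (s)", ylab = "current (pA)", ...)
  invisible(x)
}

#' Simulate a voltage-clamp trace series
#'
#' Generates one [current_trace()] per protocol level from the two-process
#' conduction model: leak current, quantized stochastically gating pores,
#' biexponential jump transients, optional baseline drift, white noise, and
#' causal low-pass filtering. `mode = "blm"` forces the polarization offset
#' to zero (flat bilayer); `mode = "patch"` keeps it. Each per-level trace
#' consists of a holding segment (with the decay of the return jump from
#' the previous level) followed by the voltage step.
#'
#' The same master `seed` with identical parameters yields a bit-identical
#' series; per-level substreams are derived deterministically so each level
#' is independently reproducible.
#'
#' @param protocol a [build_protocol()] object.
#' @param cs a [conductance_set()]; pores conduct `g_single_S` each (when
#'   `n_pores`/`g_single_S` are unset, `g_pores_S` is used with the mean
#'   gating mode).
#' @param pe a [pore_energetics()].
#' @param env a [recording_env()].
#' @param gk a [gating_kinetics()].
#' @param tp a [transient_params()], or `NULL` for no transients.
#' @param nm a [noise_model()], or `NULL` for noise-free, unfiltered output.
#' @param seed integer master seed.
#' @param mode `"patch"` (offset retained) or `"blm"` (offset forced to 0).
#' @param gating `"stochastic"` (Markov pore counts) or `"mean"`
#'   (deterministic expected conduction `g_p * P_open(V)`).
#' @param drift_A_per_s optional linear baseline drift (default 0).
#' @param depth_mm optional condition label recorded in metadata.
#' @return An object of class `"trace_series"`: a list of `current_trace`
#'   objects, one per level.
#' @export
simulate_trace <- function(protocol, cs, pe, env = recording_env(),
                           gk = gating_kinetics(), tp = NULL, nm = NULL,
                           seed = 1L, mode = c("patch", "blm"),
                           gating = c("stochastic", "mean"),
                           drift_A_per_s = 0, depth_mm = NULL) {
  mode <- match.arg(mode)
  gating <- match.arg(gating)
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(cs, "conductance_set"),
            inherits(pe, "pore_energetics"))
  pe_eff <- if (mode == "blm")
    pore_energetics(pe$dmu0_kT, pe$alpha_kT_per_V2, 0) else pe
  fs <- protocol$sample_rate_Hz
  dt <- 1 / fs
  n_pre <- round(protocol$pre_step_s * fs)
  n_step <- round(protocol$step_s * fs)
  e0 <- env$nernst_V
  hold <- protocol$holding_V

  n_pores <- if (!is.null(cs$n_pores)) cs$n_pores else 0L
  g_single <- if (!is.null(cs$g_single_S)) cs$g_single_S else 0
  use_stochastic <- gating == "stochastic" && n_pores > 0L

  traces <- vector("list", protocol$n_levels)
  prev_level <- hold
  for (i in seq_len(protocol$n_levels)) {
    lev <- protocol$levels_V[i]
    level_seed <- (as.integer(seed) %% 100000L) * 20011L + i
    set.seed(level_seed)

    t_all <- seq(0, by = dt, length.out = n_pre + n_step)
    v_all <- c(rep(hold, n_pre), rep(lev, n_step))

    # conduction
    if (use_stochastic) {
      gs_pre <- simulate_gating(pe_eff, gk, n_pores, hold, n_pre * dt,
                                sample_rate_Hz = fs)
      gs_step <- simulate_gating(pe_eff, gk, n_pores, lev, n_step * dt,
                                 sample_rate_Hz = fs,
                                 p_init = open_probability(pe_eff, hold))
      n_open <- c(gs_pre$n_open[seq_len(n_pre)],
                  gs_step$n_open[seq_len(n_step)])
      i_cond <- (cs$g_leak_S + g_single * n_open) * (v_all - e0)
      true_openings <- gs_step$n_openings
      true_open_fraction <- gs_step$open_fraction
    } else {
      i_cond <- (cs$g_leak_S +
                   cs$g_pores_S * open_probability(pe_eff, v_all)) *
        (v_all - e0)
      true_openings <- NA_integer_
      true_open_fraction <- open_probability(pe_eff, lev)
    }

    # jump transients: return jump (prev level -> holding) at t = 0 and
    # step jump (holding -> level) at t = pre_step_s
    i_trans <- numeric(n_pre + n_step)
    if (!is.null(tp)) {
      if (prev_level != hold) {
        amp <- transient_amplitudes(tp, prev_level, hold)
        i_trans <- i_trans + transient_curve(t_all, amp$a0, amp$am,
                                             tp$tau_fast_s, tp$tau_slow_s)
      }
      if (lev != hold) {
        amp <- transient_amplitudes(tp, hold, lev)
        idx <- seq(n_pre + 1L, n_pre + n_step)
        i_trans[idx] <- i_trans[idx] +
          transient_curve(t_all[idx] - t_all[n_pre + 1L],
                          amp$a0, amp$am, tp$tau_fast_s, tp$tau_slow_s)
      }
    }

    i_tot <- i_cond + i_trans + drift_A_per_s * t_all
    if (!is.null(nm)) {
      if (nm$current_noise_sd_A > 0)
        i_tot <- i_tot + stats::rnorm(length(i_tot), 0,
                                      nm$current_noise_sd_A)
      i_tot <- apply_lowpass(i_tot, fs, nm$filter_cutoff_Hz,
                             nm$filter_order)
    }

    md <- list(format_version = 1L,
               level_V = lev, holding_V = hold,
               pre_step_s = protocol$pre_step_s, step_s = protocol$step_s,
               sample_rate_Hz = fs, seed = seed, level_seed = level_seed,
               mode = mode, gating = gating, depth_mm = depth_mm,
               g_leak_S = cs$g_leak_S, g_pores_S = cs$g_pores_S,
               g_single_S = g_single, n_pores = n_pores,
               dmu0_kT = pe_eff$dmu0_kT,
               alpha_kT_per_V2 = pe_eff$alpha_kT_per_V2,
               offset_V = pe_eff$offset_V, nernst_V = e0,
               mean_open_lifetime_s = gk$mean_open_lifetime_s,
               tau_fast_s = if (!is.null(tp)) tp$tau_fast_s else NA,
               tau_slow_s = if (!is.null(tp)) tp$tau_slow_s else NA,
               a0_per_V = if (!is.null(tp)) tp$a0_per_V else NA,
               am_per_V = if (!is.null(tp)) tp$am_per_V else NA,
               noise_sd_A = if (!is.null(nm)) nm$current_noise_sd_A else 0,
               filter_cutoff_Hz = if (!is.null(nm)) nm$filter_cutoff_Hz else NA,
               filter_order = if (!is.null(nm)) nm$filter_order else NA,
               drift_A_per_s = drift_A_per_s,
               true_openings = true_openings,
               true_open_fraction = true_open_fraction)
    traces[[i]] <- current_trace(t_all, v_all, i_tot, md)
    prev_level <- lev
  }
  structure(traces, class = "trace_series")
}

#' @export
print.trace_series <- function(x, ...) {
  levs <- vapply(x, function(tr) attr(tr, "metadata")$level_V, numeric(1))
  cat(sprintf("Trace series: %d levels (%g to %g mV), %d samples each\n",
              length(x), 1e3 * levs[1], 1e3 * levs[length(levs)],
              nrow(x[[1]])))
  invisible(x)
}

#' Scale conductances for a depth condition
#'
#' Hydrostatic pressure across the patch grows with pipette depth, and both
#' the leak and pore conductances grow with it. This helper applies a
#' user-chosen multiplicative rule and labels the result with the depth;
#' it makes no mechanistic claim about the scaling.
#'
#' @param cs a [conductance_set()].
#' @param depth_mm pipette depth below the bath surface in mm (>= 0).
#' @param g_leak_factor multiplier for the leak conductance.
#' @param g_pores_factor multiplier for the pore conductances (applied to
#'   both `g_single_S` and the total `g_pores_S`).
#' @return A `conductance_set` with a `depth_mm` attribute.
#' @export
depth_condition <- function(cs, depth_mm, g_leak_factor = 1,
                            g_pores_factor = 1) {
  stopifnot(inherits(cs, "conductance_set"), depth_mm >= 0,
            g_leak_factor > 0, g_pores_factor > 0)
  out <- conductance_set(
    g_leak_S = cs$g_leak_S * g_leak_factor,
    g_single_S = if (!is.null(cs$g_single_S))
      cs$g_single_S * g_pores_factor else NULL,
    n_pores = cs$n_pores,
    g_pores_S = if (is.null(cs$g_single_S) || is.null(cs$n_pores))
      cs$g_pores_S * g_pores_factor else NULL)
  attr(out, "depth_mm") <- depth_mm
  out
}
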