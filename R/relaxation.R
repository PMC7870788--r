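# Post-jump current transients: forward model from a structural
# decomposition, and biexponential fitting with relaxation times shared
# across all jumps of a series.
#
# The decomposition (dCm, d(A P0), dg) is NOT identifiable from the fitted
# (A0, Am, plateau) of a single jump; the fitter therefore estimates lumped
# amplitudes only and the decomposition exists strictly as a forward model.

#' Structural decomposition of a jump transient
#'
#' Steady-state capacitance, conductance and polarization charge before
#' and after a voltage jump. After a jump the current relaxes with two
#' time scales: a fast one (charging the membrane capacitor through the
#' electrolyte) and a slow one (structural relaxation of the membrane that
#' changes its capacitance, polarization and conductance).
#'
#' @param cap_before_F,cap_after_F membrane capacitance before/after (>= 0).
#' @param g_before_S,g_after_S membrane conductance before/after.
#' @param pol_charge_before_C,pol_charge_after_C spontaneous polarization
#'   charge `A * P0` before/after.
#' @return An object of class `"transient_decomposition"` with the deltas
#'   (`d_cap_F`, `d_g_S`, `d_pol_charge_C`) precomputed as after - before.
#' @export
transient_decomposition <- function(cap_before_F, cap_after_F,
                                    g_before_S, g_after_S,
                                    pol_charge_before_C = 0,
                                    pol_charge_after_C = 0) {
  stopifnot(cap_before_F >= 0, cap_after_F >= 0)
  structure(list(cap_before_F = cap_before_F, cap_after_F = cap_after_F,
                 g_before_S = g_before_S, g_after_S = g_after_S,
                 pol_charge_before_C = pol_charge_before_C,
                 pol_charge_after_C = pol_charge_after_C,
                 d_cap_F = cap_after_F - cap_before_F,
                 d_g_S = g_after_S - g_before_S,
                 d_pol_charge_C = pol_charge_after_C - pol_charge_before_C),
            class = "transient_decomposition")
}

#' Forward post-jump current from a structural decomposition
#'
#' Evaluates the biexponential transient exactly:
#' \deqn{I(t) = g_a V_a + A_0 e^{-t/\tau_0} + A_m e^{-t/\tau_m}}
#' with \eqn{A_0 = C_{m,b}\Delta V/\tau_0} (capacitor charging) and
#' \eqn{A_m = (\Delta C_m V_a + \Delta(AP_0))/\tau_m - \Delta g\, V_a}
#' (membrane relaxation). The \eqn{t \to \infty} limit is the steady-state
#' current \eqn{g_a V_a}.
#'
#' @param td a [transient_decomposition()].
#' @param v_before,v_after voltages before and after the jump, volts.
#' @param tau0,taum fast and slow time constants, `0 < tau0 < taum`.
#' @param t time grid in seconds, measured from the jump.
#' @return A list with `current_A` (the series), the amplitudes `a0_A`,
#'   `am_A`, and the plateau `plateau_A = g_after_S * v_after`.
#' @export
forward_transient <- function(td, v_before, v_after, tau0 = 258e-6,
                              taum = 1.74e-3, t) {
  stopifnot(inherits(td, "transient_decomposition"), tau0 > 0, taum > tau0)
  dv <- v_after - v_before
  a0 <- td$cap_before_F * dv / tau0
  am <- (td$d_cap_F * v_after + td$d_pol_charge_C) / taum -
    td$d_g_S * v_after
  plateau <- td$g_after_S * v_after
  list(current_A = plateau + a0 * exp(-t / tau0) + am * exp(-t / taum),
       a0_A = a0, am_A = am, plateau_A = plateau,
       tau0_s = tau0, taum_s = taum)
}

# pull aligned jump segments out of a trace series: time from step onset,
# current, and the jump voltages
jump_segments <- function(traces, window_s = 0.05) {
  segs <- list()
  for (tr in traces) {
    stopifnot(inherits(tr, "current_trace"))
    md <- attr(tr, "metadata")
    onset <- if (!is.null(md$pre_step_s)) md$pre_step_s else 0
    rel <- tr$time_s - tr$time_s[1] - onset
    idx <- rel >= 0 & rel < window_s
    segs[[length(segs) + 1L]] <-
      list(t = rel[idx], current_A = tr$current_A[idx],
           level_V = md$level_V,
           dv_V = md$level_V - if (!is.null(md$holding_V))
             md$holding_V else 0)
  }
  segs
}

# linear inner stage: given taus, per-segment LS for (plateau, A0, Am)
relax_inner <- function(segs, tau0, taum, exclude_initial_s) {
  out <- vector("list", length(segs))
  total_rss <- 0
  for (j in seq_along(segs)) {
    s <- segs[[j]]
    keep <- s$t >= exclude_initial_s
    t <- s$t[keep]; y <- s$current_A[keep]
    X <- cbind(1, exp(-t / tau0), exp(-t / taum))
    if (length(y) <= ncol(X))
      stop("fewer samples than parameters in a jump segment")
    cf <- stats::lm.fit(X, y)$coefficients
    res <- y - X %*% cf
    rss <- sum(res^2)
    total_rss <- total_rss + rss
    out[[j]] <- data.frame(level_V = s$level_V, dv_V = s$dv_V,
                           plateau_A = cf[1], amp_fast_A = cf[2],
                           amp_slow_A = cf[3], rss = rss,
                           n = length(y))
  }
  list(table = do.call(rbind, out), rss = total_rss)
}

#' Biexponential relaxation fit with shared time constants
#'
#' Fits \eqn{I(t) = plateau + A_0 e^{-t/\tau_0} + A_m e^{-t/\tau_m}} to the
#' post-jump segment of every trace in a series. A two-stage scheme is
#' used: a global nonlinear search over the two time constants -- shared
#' across all jumps of the series, since both reflect membrane-level
#' processes -- wrapped around exact per-jump linear least squares for the
#' three amplitudes. The first `exclude_initial_s` of every segment (one
#' sample interval, the resolution limit of the recording) is dropped.
#'
#' @param traces a `trace_series` or list of [current_trace()] objects, or
#'   a list of precomputed segments (`t`, `current_A`, `level_V`, `dv_V`).
#' @param exclude_initial_s initial dead time dropped from each segment.
#' @param window_s length of the fitted segment after the jump.
#' @param shared_taus fit one (tau0, taum) pair for the whole series
#'   (default); `FALSE` fits time constants per jump.
#' @param fixed_tau_fast optional fixed value of tau0 (the fast constant is
#'   often pinned by the recording filter); only taum is then searched.
#' @param tau_starts optional starting values `c(tau0, taum)`; defaults to
#'   3 sample intervals and 10 times that.
#' @return An object of class `"relax_fit"`: shared `tau_fast_s`,
#'   `tau_slow_s`, and a per-jump `table` of (level, dV, plateau, A0, Am,
#'   RSS, n).
#' @export
fit_relaxation <- function(traces, exclude_initial_s = 1e-4,
                           window_s = 0.05, shared_taus = TRUE,
                           fixed_tau_fast = NULL, tau_starts = NULL) {
  segs <- if (length(traces) > 0 && inherits(traces[[1]], "current_trace"))
    jump_segments(traces, window_s) else traces
  if (length(segs) < 1) stop("no jump segments to fit")
  dt <- if (length(segs[[1]]$t) > 1) diff(segs[[1]]$t[1:2]) else 1e-4
  if (is.null(tau_starts)) tau_starts <- c(3 * dt, 30 * dt)

  fit_one_set <- function(ss) {
    if (!is.null(fixed_tau_fast)) {
      obj <- function(lr) {
        taum <- fixed_tau_fast * (1 + exp(lr))
        relax_inner(ss, fixed_tau_fast, taum, exclude_initial_s)$rss
      }
      op <- stats::optimize(obj, c(log(0.05), log(1e4)))
      tau0 <- fixed_tau_fast
      taum <- fixed_tau_fast * (1 + exp(op$minimum))
    } else {
      # theta = (log tau0, log(taum/tau0 - 1)) keeps tau0 < taum
      obj <- function(th) {
        tau0 <- exp(th[1]); taum <- tau0 * (1 + exp(th[2]))
        relax_inner(ss, tau0, taum, exclude_initial_s)$rss
      }
      th0 <- c(log(tau_starts[1]), log(tau_starts[2] / tau_starts[1] - 1))
      op <- stats::optim(th0, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 2000))
      # one restart from the solution guards against premature simplex
      # collapse on flat valleys
      op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 2000))
      tau0 <- exp(op$par[1]); taum <- tau0 * (1 + exp(op$par[2]))
    }
    inner <- relax_inner(ss, tau0, taum, exclude_initial_s)
    list(tau0 = tau0, taum = taum, inner = inner)
  }

  if (shared_taus) {
    f <- fit_one_set(segs)
    tab <- f$inner$table
    tab$tau_fast_s <- f$tau0
    tab$tau_slow_s <- f$taum
    tau0 <- f$tau0; taum <- f$taum; rss <- f$inner$rss
  } else {
    rows <- lapply(segs, function(s) {
      f <- fit_one_set(list(s))
      cbind(f$inner$table, tau_fast_s = f$tau0, tau_slow_s = f$taum)
    })
    tab <- do.call(rbind, rows)
    tau0 <- stats::median(tab$tau_fast_s)
    taum <- stats::median(tab$tau_slow_s)
    rss <- sum(tab$rss)
  }
  rownames(tab) <- NULL
  structure(list(tau_fast_s = tau0, tau_slow_s = taum, table = tab,
                 shared_taus = shared_taus, rss = rss,
                 exclude_initial_s = exclude_initial_s),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("Biexponential relaxation fit (%s time constants)\n",
              if (x$shared_taus) "shared" else "per-jump"))
  cat(sprintf("  tau_fast = %.4g us, tau_slow = %.4g ms; %d jumps, RSS %.4g\n",
              1e6 * x$tau_fast_s, 1e3 * x$tau_slow_s, nrow(x$table),
              x$rss))
  invisible(x)
}

#' @export
coef.relax_fit <- function(object, ...) {
  c(tau_fast_s = object$tau_fast_s, tau_slow_s = object$tau_slow_s)
}

#' @export
summary.relax_fit <- function(object, ...) {
  print(object)
  df <- object$table
  df$level_V <- 1e3 * df$level_V
  names(df)[names(df) == "level_V"] <- "level_mV"
  print(data.frame(lapply(df, signif, 4)), row.names = FALSE)
  invisible(object)
}

#' Classify relaxation amplitudes by their voltage dependence
#'
#' The slow amplitude is expected to be linear in the jump voltage, while
#' the fast amplitude tracks the (possibly rectified) steady-state I-V
#' relation. Each amplitude is fitted as `A(V) = a * V`; it is classified
#' `"rectified"` when its residual pattern correlates with the
#' nonlinearity of the I-V profile (the profile minus its best straight
#' line through the reversal point), and `"linear"` otherwise.
#'
#' @param rf a `"relax_fit"`.
#' @param iv an [iv_profile()] measured on the same series (voltages must
#'   cover the fitted jump levels).
#' @param cor_threshold correlation of residual patterns above which an
#'   amplitude is called rectified.
#' @return A data.frame with one row per amplitude component:
#'   `slope_A_per_V`, `residual_cor`, `class`.
#' @export
amplitude_voltage_analysis <- function(rf, iv, cor_threshold = 0.6) {
  stopifnot(inherits(rf, "relax_fit"), inherits(iv, "iv_profile"))
  tab <- rf$table
  if (nrow(tab) < 5) stop("need at least 5 jumps")
  # I-V nonlinearity at the jump voltages
  use <- !iv$excluded
  g_lin <- sum(iv$mean_current_A[use] * iv$voltage_V[use]) /
    sum(iv$voltage_V[use]^2)
  iv_resid <- stats::approx(iv$voltage_V[use],
                            iv$mean_current_A[use] -
                              g_lin * iv$voltage_V[use],
                            xout = tab$level_V, rule = 2)$y
  classify <- function(amp) {
    v <- tab$level_V
    if (all(amp == 0)) {
      return(data.frame(slope_A_per_V = 0, residual_cor = NA_real_,
                        class = "linear"))
    }
    a <- sum(amp * v) / sum(v^2)
    res <- amp - a * v
    rel <- sum(res^2) / sum(amp^2)
    if (rel < 1e-6 || stats::sd(res) == 0 || stats::sd(iv_resid) == 0) {
      return(data.frame(slope_A_per_V = a, residual_cor = NA_real_,
                        class = "linear"))
    }
    r <- stats::cor(res, iv_resid)
    data.frame(slope_A_per_V = a, residual_cor = r,
               class = if (isTRUE(abs(r) > cor_threshold)) "rectified"
               else "linear")
  }
  out <- rbind(classify(tab$amp_fast_A), classify(tab$amp_slow_A))
  out$component <- c("fast", "slow")
  out[, c("component", "slope_A_per_V", "residual_cor", "class")]
}
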