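# Steady-state I-V extraction and two-process model fitting.
#
# The fit target is I(V) = (g_L + g_p * P_open(V)) (V - E0) with P_open from
# the quadratic pore free energy. Because g_p and exp(-dmu(0)) are nearly
# degenerate when P_open << 1 over the observed range, the fitter works in
# the reparameterization (g_p, V0, p_min, alpha), where
# p_min = P_open(-V0) is the minimum open probability.

#' Construct a steady-state I-V profile
#'
#' Per-level summary of tail currents: mean, standard deviation and sample
#' count of the current over the analysis window at each step voltage,
#' with per-level exclusion flags.
#'
#' @param voltage_V step voltages.
#' @param mean_current_A,sd_current_A,n per-level summaries; sd must be
#'   non-negative.
#' @param excluded logical exclusion markers (e.g. the first jump of a
#'   series, which has not equilibrated).
#' @return An object of class `"iv_profile"` (a data.frame).
#' @export
iv_profile <- function(voltage_V, mean_current_A,
                       sd_current_A = rep(0, length(voltage_V)),
                       n = rep(1L, length(voltage_V)),
                       excluded = rep(FALSE, length(voltage_V))) {
  stopifnot(length(mean_current_A) == length(voltage_V),
            all(is.finite(voltage_V)), all(is.finite(mean_current_A)),
            all(sd_current_A >= 0))
  out <- data.frame(voltage_V = voltage_V,
                    mean_current_A = mean_current_A,
                    sd_current_A = sd_current_A,
                    n = n, excluded = excluded)
  class(out) <- c("iv_profile", "data.frame")
  out
}

#' @export
print.iv_profile <- function(x, ...) {
  cat(sprintf("I-V profile: %d levels (%d excluded)\n", nrow(x),
              sum(x$excluded)))
  df <- data.frame(`V (mV)` = 1e3 * x$voltage_V,
                   `I (pA)` = signif(1e12 * x$mean_current_A, 4),
                   `sd (pA)` = signif(1e12 * x$sd_current_A, 3),
                   n = x$n, excluded = x$excluded, check.names = FALSE)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Subtract the holding-voltage offset from a trace
#'
#' Small amplifier offsets are removed by subtracting the mean current of
#' the holding segment (the part of the trace recorded at the holding
#' voltage before the step) from the entire trace. Only the settled second
#' half of the holding segment is averaged, so the decaying transient of
#' the preceding jump does not bias the reference.
#'
#' @param trace a [current_trace()] containing a holding segment.
#' @return The corrected `current_trace`.
#' @export
correct_offset <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  md <- attr(trace, "metadata")
  if (is.null(md$pre_step_s) || md$pre_step_s <= 0)
    stop("trace has no holding segment")
  rel <- trace$time_s - trace$time_s[1]
  hold_idx <- rel >= md$pre_step_s / 2 & rel < md$pre_step_s
  if (!any(hold_idx)) stop("trace has no holding segment")
  trace$current_A <- trace$current_A - mean(trace$current_A[hold_idx])
  attr(trace, "metadata")$offset_corrected <- TRUE
  trace
}

#' Extract a steady-state I-V profile from a trace series
#'
#' Averages the tail of each current trace -- by default 1.5 to 3 s after
#' step onset, i.e. the second half of a 3.1 s step, when the transients
#' have long decayed -- into one mean and sd per voltage level.
#'
#' @param traces a `trace_series` or list of [current_trace()] objects.
#' @param window_s two-element window relative to step onset, seconds.
#' @param discard_first flag the first level of the series as excluded (the
#'   first jump of a series is systematically an outlier because the
#'   membrane has not yet equilibrated).
#' @return An [iv_profile()].
#' @export
extract_iv <- function(traces, window_s = c(1.5, 3.0),
                       discard_first = FALSE) {
  stopifnot(is.list(traces), length(traces) >= 1,
            length(window_s) == 2, window_s[2] > window_s[1])
  v <- m <- s <- numeric(length(traces))
  n <- integer(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "current_trace"))
    md <- attr(tr, "metadata")
    onset <- if (!is.null(md$pre_step_s)) md$pre_step_s else 0
    if (window_s[1] >= md$step_s)
      stop("analysis window lies outside the step duration")
    rel <- tr$time_s - tr$time_s[1] - onset
    idx <- rel >= window_s[1] & rel < window_s[2]
    if (!any(idx)) stop("empty analysis window")
    v[i] <- if (!is.null(md$level_V)) md$level_V else
      stats::median(tr$voltage_V[idx])
    m[i] <- mean(tr$current_A[idx])
    s[i] <- stats::sd(tr$current_A[idx])
    if (is.na(s[i])) s[i] <- 0
    n[i] <- sum(idx)
  }
  excl <- rep(FALSE, length(traces))
  if (discard_first) excl[1] <- TRUE
  iv_profile(v, m, s, n, excl)
}

# internal: model current under the fitting reparameterization
# theta: named list g_leak_S, g_pores_S, offset_V, p_min, alpha
iv_model_current <- function(v, g_leak_S, g_pores_S, offset_V, p_min,
                             alpha, e0 = 0) {
  eta <- stats::qlogis(p_min)
  p <- stats::plogis(alpha * (v + offset_V)^2 + eta)
  (g_leak_S + g_pores_S * p) * (v - e0)
}

iv_weights <- function(profile) {
  sd <- profile$sd_current_A
  n <- profile$n
  se <- ifelse(n > 0, sd / sqrt(pmax(n, 1)), sd)
  pos <- se[se > 0]
  if (length(pos) == 0) return(rep(1, nrow(profile)))
  se[se <= 0] <- min(pos)
  1 / se^2
}

new_iv_fit <- function(scenario, est, se, rss, profile, e0, fitted,
                       converged = TRUE, n_used = NA_integer_,
                       message = "") {
  structure(list(scenario = scenario, coefficients = est, se = se,
                 rss = rss, profile = profile, nernst_V = e0,
                 fitted_A = fitted, converged = converged,
                 n_used = n_used, message = message),
            class = "iv_fit")
}

#' Linear (leak-only) fit of an I-V profile
#'
#' Weighted least-squares slope through the reversal point
#' (`I(E0) = 0`), appropriate for traces without pore activity. The slope
#' is the leak conductance.
#'
#' @param profile an [iv_profile()].
#' @param e0 Nernst potential in volts.
#' @return An `"iv_fit"` object with scenario `"linear"`.
#' @export
fit_linear <- function(profile, e0 = 0) {
  stopifnot(inherits(profile, "iv_profile"))
  use <- !profile$excluded
  if (sum(use) < 2) stop("need at least 2 usable points for a linear fit")
  v <- profile$voltage_V[use] - e0
  i <- profile$mean_current_A[use]
  w <- iv_weights(profile)[use]
  g <- sum(w * v * i) / sum(w * v^2)
  res <- i - g * v
  dof <- sum(use) - 1L
  s2 <- sum(w * res^2) / max(dof, 1L)
  se_g <- sqrt(s2 / sum(w * v^2))
  fitted <- g * (profile$voltage_V - e0)
  new_iv_fit("linear",
             est = c(g_leak_S = g, g_pores_S = 0, offset_V = NA,
                     dmu0_kT = NA, alpha_kT_per_V2 = NA, p_min = NA),
             se = c(g_leak_S = se_g),
             rss = sum(w * res^2), profile = profile, e0 = e0,
             fitted = fitted, n_used = sum(use))
}

#' Fit the two-process pore model to an I-V profile
#'
#' Weighted nonlinear least squares of the steady-state current
#' \eqn{I(V) = (g_L + g_p P_{open}(V))(V - E_0)} under one of three
#' scenarios: conduction by pores only (`g_L = 0`), pores plus a fixed leak
#' taken from a linear recording of the same membrane, or pores plus a
#' freely fitted leak. (`scenario = "linear"` delegates to [fit_linear()].)
#'
#' The pore term is parameterized by the total open-pore conductance
#' \eqn{g_p}, the offset \eqn{V_0}, the minimum open probability
#' \eqn{p_{min} = P_{open}(-V_0)} and the curvature \eqn{\alpha}; the
#' reported \eqn{\Delta\mu(0)} is derived from these. Optimization is
#' multi-started over a grid of \eqn{V_0} values (-0.3 to 0.3 V in 0.05 V
#' steps); the best residual sum of squares wins, ties broken in favour of
#' the smaller \eqn{|V_0|}.
#'
#' @param profile an [iv_profile()].
#' @param scenario one of `"free_leak"`, `"fixed_leak"`, `"pores_only"`,
#'   `"linear"`.
#' @param fixed_g_leak_S leak conductance in siemens, required for
#'   `"fixed_leak"`.
#' @param e0 Nernst potential in volts.
#' @param v0_starts multi-start grid for the offset.
#' @param control list overriding `ftol`/`ptol` (default 1e-10) and
#'   `maxiter` (default 500) of the Levenberg-Marquardt optimizer.
#' @return An object of class `"iv_fit"` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot` and `simulate` methods.
#'   Diagnostics include `min_open_probability` (the fitted \eqn{p_{min}},
#'   attained at \eqn{V = -V_0}).
#' @examples
#' pe <- pore_energetics(4, 40, 0.2)
#' cs <- conductance_set(g_leak_S = 0.37e-9, g_pores_S = 1.5e-9)
#' v <- seq(-0.2, 0.2, 0.025)
#' prof <- iv_profile(v, steady_state_current(cs, pe, recording_env(), v))
#' fit <- fit_iv(prof, "free_leak")
#' coef(fit)[["offset_V"]]
#' @export
fit_iv <- function(profile, scenario = c("free_leak", "fixed_leak",
                                         "pores_only", "linear"),
                   fixed_g_leak_S = NULL, e0 = 0,
                   v0_starts = seq(-0.3, 0.3, by = 0.05),
                   control = list()) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(profile, "iv_profile"))
  if (scenario == "linear") return(fit_linear(profile, e0))
  if (scenario == "fixed_leak" && is.null(fixed_g_leak_S))
    stop("scenario 'fixed_leak' requires fixed_g_leak_S")
  use <- !profile$excluded & is.finite(profile$mean_current_A)
  if (sum(use) < 6)
    stop("need at least 6 usable points for a nonlinear scenario")
  v <- profile$voltage_V[use]
  iobs <- profile$mean_current_A[use]
  w <- iv_weights(profile)[use]
  sw <- sqrt(w)

  ctrl <- utils::modifyList(list(ftol = 1e-10, ptol = 1e-10,
                                 maxiter = 500), control)
  free_leak <- scenario == "free_leak"
  g_leak_fixed <- switch(scenario, pores_only = 0,
                         fixed_leak = fixed_g_leak_S, free_leak = NA)

  # crude initial scales from the data
  slope <- iobs / ifelse(abs(v - e0) < 1e-6, NA, v - e0)
  g_lo <- max(stats::quantile(slope, 0.25, na.rm = TRUE, names = FALSE),
              1e-13)
  g_hi <- max(slope, na.rm = TRUE)
  gp0 <- max(g_hi - g_lo, 0.2 * g_lo, 1e-13)
  gl0 <- if (free_leak) g_lo else g_leak_fixed

  resid_fun <- function(par) {
    g_l <- if (free_leak) exp(par[["log_gl"]]) else g_leak_fixed
    im <- iv_model_current(v, g_l, exp(par[["log_gp"]]), par[["v0"]],
                           stats::plogis(par[["eta"]]),
                           exp(par[["log_alpha"]]), e0)
    sw * (im - iobs)
  }

  best <- NULL
  for (v0s in v0_starts) {
    par0 <- c(log_gp = log(gp0), v0 = v0s, eta = stats::qlogis(0.01),
              log_alpha = log(40))
    if (free_leak) par0 <- c(par0, log_gl = log(gl0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = ctrl$ftol, ptol = ctrl$ptol,
                           maxiter = ctrl$maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$deviance
    if (is.null(best) ||
        rss < best$rss * (1 - 1e-9) ||
        (abs(rss - best$rss) <= best$rss * 1e-9 &&
         abs(fit$par[["v0"]]) < abs(best$fit$par[["v0"]]))) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("I-V fit failed to converge from every start of the V0 grid (",
         length(v0_starts), " starts, scenario '", scenario, "')")

  par <- best$fit$par
  g_l <- if (free_leak) exp(par[["log_gl"]]) else g_leak_fixed
  g_p <- exp(par[["log_gp"]])
  v0 <- par[["v0"]]
  p_min <- stats::plogis(par[["eta"]])
  alpha <- exp(par[["log_alpha"]])
  # dmu(0) back from p_min: dmu_peak = -qlogis(p_min) = dmu(0) + alpha V0^2
  dmu0 <- -stats::qlogis(p_min) - alpha * v0^2

  # delta-method standard errors on the natural scale
  se <- rep(NA_real_, 5)
  names(se) <- c("g_leak_S", "g_pores_S", "offset_V", "p_min",
                 "alpha_kT_per_V2")
  sm <- tryCatch(summary(best$fit), error = function(e) NULL)
  if (!is.null(sm)) {
    ses <- sm$coefficients[, "Std. Error"]
    se[["g_pores_S"]] <- g_p * ses[["log_gp"]]
    se[["offset_V"]] <- ses[["v0"]]
    se[["p_min"]] <- p_min * (1 - p_min) * ses[["eta"]]
    se[["alpha_kT_per_V2"]] <- alpha * ses[["log_alpha"]]
    if (free_leak) se[["g_leak_S"]] <- g_l * ses[["log_gl"]]
  }

  fitted <- iv_model_current(profile$voltage_V, g_l, g_p, v0, p_min,
                             alpha, e0)
  new_iv_fit(scenario,
             est = c(g_leak_S = g_l, g_pores_S = g_p, offset_V = v0,
                     dmu0_kT = dmu0, alpha_kT_per_V2 = alpha,
                     p_min = p_min),
             se = se, rss = best$rss, profile = profile, e0 = e0,
             fitted = fitted, converged = best$fit$info %in% 1:4,
             n_used = sum(use), message = best$fit$message)
}

#' @export
print.iv_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Two-process I-V fit (scenario: %s)\n", x$scenario))
  cat(sprintf("  g_leak  = %.4g pS\n", 1e12 * cf[["g_leak_S"]]))
  if (x$scenario != "linear") {
    cat(sprintf("  g_pores = %.4g pS\n", 1e12 * cf[["g_pores_S"]]))
    cat(sprintf("  V0      = %.1f mV\n", 1e3 * cf[["offset_V"]]))
    cat(sprintf("  dmu(0)  = %.3g kT, alpha = %.3g kT/V^2\n",
                cf[["dmu0_kT"]], cf[["alpha_kT_per_V2"]]))
    cat(sprintf("  min P_open = %.3g at V = %.1f mV\n",
                cf[["p_min"]], -1e3 * cf[["offset_V"]]))
  }
  cat(sprintf("  weighted RSS = %.4g on %d points\n", x$rss, x$n_used))
  invisible(x)
}

#' @export
summary.iv_fit <- function(object, ...) {
  cf <- object$coefficients
  nm <- names(cf)
  tab <- data.frame(estimate = as.numeric(cf),
                    std_error = as.numeric(object$se[match(nm,
                      names(object$se))]),
                    row.names = nm)
  out <- list(scenario = object$scenario, coefficients = tab,
              rss = object$rss, n_used = object$n_used,
              min_open_probability = unname(cf[["p_min"]]),
              min_open_probability_V = unname(-cf[["offset_V"]]),
              converged = object$converged)
  class(out) <- "summary.iv_fit"
  out
}

#' @export
print.summary.iv_fit <- function(x, ...) {
  cat(sprintf("Two-process I-V fit, scenario '%s' (%d points, %s)\n",
              x$scenario, x$n_used,
              if (x$converged) "converged" else "NOT converged"))
  print(signif(x$coefficients, 5))
  if (!is.na(x$min_open_probability))
    cat(sprintf("Minimum open probability %.4g at %.1f mV; weighted RSS %.4g\n",
                x$min_open_probability, 1e3 * x$min_open_probability_V,
                x$rss))
  invisible(x)
}

#' @export
coef.iv_fit <- function(object, ...) object$coefficients

#' @export
fitted.iv_fit <- function(object, ...) object$fitted_A

#' @export
residuals.iv_fit <- function(object, ...) {
  object$profile$mean_current_A - object$fitted_A
}

#' Predicted steady-state current from a fitted I-V model
#'
#' @param object an `"iv_fit"`.
#' @param newdata voltages in volts (default: the fitted profile's levels).
#' @param ... unused.
#' @return Currents in amperes.
#' @export
predict.iv_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$profile$voltage_V else newdata
  cf <- object$coefficients
  if (object$scenario == "linear")
    return(cf[["g_leak_S"]] * (v - object$nernst_V))
  iv_model_current(v, cf[["g_leak_S"]], cf[["g_pores_S"]],
                   cf[["offset_V"]], cf[["p_min"]],
                   cf[["alpha_kT_per_V2"]], object$nernst_V)
}

#' @export
plot.iv_fit <- function(x, ...) {
  p <- x$profile
  vmV <- 1e3 * p$voltage_V
  graphics::plot(vmV, 1e12 * p$mean_current_A,
                 pch = ifelse(p$excluded, 1, 19),
                 xlab = "voltage (mV)", ylab = "current (pA)", ...)
  vg <- seq(min(p$voltage_V), max(p$voltage_V), length.out = 200)
  graphics::lines(1e3 * vg, 1e12 * predict(x, vg))
  invisible(x)
}

#' Simulate I-V profiles from a fitted model
#'
#' Draws new per-level mean currents as the fitted curve plus Gaussian
#' noise with each level's standard error.
#'
#' @param object an `"iv_fit"`.
#' @param nsim number of simulated profiles.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of [iv_profile()] objects.
#' @export
simulate.iv_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$profile
  se <- ifelse(p$n > 0, p$sd_current_A / sqrt(pmax(p$n, 1)), 0)
  mu <- predict(object)
  lapply(seq_len(nsim), function(k) {
    iv_profile(p$voltage_V, mu + stats::rnorm(nrow(p), 0, se),
               p$sd_current_A, p$n, p$excluded)
  })
}

#' Detect negative-slope regions of an I-V profile
#'
#' Voltage regimes with dI/dV < 0 are impossible without a
#' voltage-dependent conductance: the pore term can make the current at
#' moderately negative voltages exceed (in magnitude) the current at
#' strongly negative ones. Centred finite differences on the sorted
#' profile are flagged where the difference quotient is negative beyond
#' twice its propagated standard error.
#'
#' @param profile an [iv_profile()].
#' @return A data.frame of voltage intervals (`v_from_V`, `v_to_V`); zero
#'   rows when none.
#' @export
detect_negative_slope <- function(profile) {
  stopifnot(inherits(profile, "iv_profile"))
  use <- which(!profile$excluded)
  if (length(use) < 3)
    stop("need at least 3 usable points")
  ord <- use[order(profile$voltage_V[use])]
  v <- profile$voltage_V[ord]
  i <- profile$mean_current_A[ord]
  se <- ifelse(profile$n[ord] > 0,
               profile$sd_current_A[ord] / sqrt(pmax(profile$n[ord], 1)), 0)
  k <- 2:(length(v) - 1)
  dv <- v[k + 1] - v[k - 1]
  slope <- (i[k + 1] - i[k - 1]) / dv
  slope_se <- sqrt(se[k + 1]^2 + se[k - 1]^2) / abs(dv)
  neg <- slope < -2 * slope_se
  if (!any(neg))
    return(data.frame(v_from_V = numeric(0), v_to_V = numeric(0)))
  # merge consecutive flagged interior points into intervals
  runs <- rle(neg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(
    v_from_V = v[k[starts[keep]] - 1L],
    v_to_V = v[k[ends[keep]] + 1L])
}

#' Compare fits across depth conditions
#'
#' Summarizes fitted offsets per condition (mean and sd of \eqn{V_0}) and
#' reports pairwise percent changes `100 * (b - a) / a` in the leak and
#' pore conductances between conditions, the convention used when
#' reporting pressure effects on membrane conduction.
#'
#' @param fits_by_condition named list; each element is a list of
#'   `"iv_fit"` objects (or a single fit) for one condition.
#' @return A list with `summary` (per-condition means/sds) and `changes`
#'   (pairwise percent changes, conditions in list order).
#' @export
compare_depths <- function(fits_by_condition) {
  stopifnot(is.list(fits_by_condition), length(fits_by_condition) >= 1)
  norm <- lapply(fits_by_condition, function(f) {
    if (inherits(f, "iv_fit")) list(f) else f
  })
  cond <- names(norm)
  if (is.null(cond)) cond <- as.character(seq_along(norm))
  getc <- function(fits, what)
    vapply(fits, function(f) unname(f$coefficients[[what]]), numeric(1))
  summ <- do.call(rbind, lapply(seq_along(norm), function(j) {
    v0 <- getc(norm[[j]], "offset_V")
    data.frame(condition = cond[j], n_fits = length(norm[[j]]),
               v0_mean_V = mean(v0), v0_sd_V = stats::sd(v0),
               g_leak_mean_S = mean(getc(norm[[j]], "g_leak_S")),
               g_pores_mean_S = mean(getc(norm[[j]], "g_pores_S")))
  }))
  changes <- NULL
  if (length(norm) >= 2) {
    pairs <- utils::combn(seq_along(norm), 2)
    changes <- do.call(rbind, apply(pairs, 2, function(pr) {
      a <- summ[pr[1], ]; b <- summ[pr[2], ]
      if (a$g_leak_mean_S == 0 || a$g_pores_mean_S == 0)
        stop("percent change undefined: zero reference conductance")
      data.frame(from = a$condition, to = b$condition,
                 g_leak_pct = 100 * (b$g_leak_mean_S - a$g_leak_mean_S) /
                   a$g_leak_mean_S,
                 g_pores_pct = 100 * (b$g_pores_mean_S - a$g_pores_mean_S) /
                   a$g_pores_mean_S)
    }))
  }
  list(summary = summ, changes = changes)
}
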