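# Hodgkin-Huxley potassium gate: the protein-channel comparison standard
# for the lipid-pore open probability. Rates are in 1/s with voltages in
# volts (absolute membrane potential convention, resting level near
# -65 mV). The sodium gates are out of scope (no rate functions available
# in this parameterization).

#' Hodgkin-Huxley potassium channel parameters
#'
#' The n-gate rate constants are fixed numerical parameterizations from
#' voltage-clamp data; only the maximal conductance is free.
#'
#' @param g_max_S maximal potassium conductance \eqn{g_{K,0}} (>= 0).
#' @return An object of class `"hh_potassium"`.
#' @export
hh_potassium <- function(g_max_S = 36e-3) {
  stopifnot(g_max_S >= 0)
  structure(list(g_max_S = g_max_S), class = "hh_potassium")
}

#' n-gate opening and closing rates
#'
#' \deqn{\alpha_n(V) = 10^4 (V + 0.055) / (1 - e^{-(V+0.055)/0.010})}
#' \deqn{\beta_n(V) = 125\, e^{-(V+0.065)/0.08}}
#' in 1/s with V in volts. The removable singularity of \eqn{\alpha_n} at
#' \eqn{V = -55} mV is evaluated by its analytic limit (100/s) via a
#' series expansion.
#'
#' @param v membrane voltage(s) in volts.
#' @return Rate(s) in 1/s.
#' @export
hh_alpha_n <- function(v) {
  x <- v + 0.055
  y <- x / 0.010
  out <- numeric(length(v))
  small <- abs(x) < 1e-7
  # x/(1 - e^{-y}) = 0.010 * y/(1-e^{-y}); y/(1-e^{-y}) ~ 1 + y/2 + y^2/12
  out[small] <- 100 * (1 + y[small] / 2 + y[small]^2 / 12)
  out[!small] <- 1e4 * x[!small] / (1 - exp(-y[!small]))
  out
}

#' @rdname hh_alpha_n
#' @export
hh_beta_n <- function(v) {
  125 * exp(-(v + 0.065) / 0.08)
}

#' Steady-state n-gate value and relaxation time
#'
#' \eqn{n_\infty = \alpha_n/(\alpha_n+\beta_n)} (strictly increasing in V,
#' within (0,1)) and \eqn{\tau_n = 1/(\alpha_n+\beta_n)} (> 0).
#'
#' @param v membrane voltage(s) in volts.
#' @return `hh_n_inf`: dimensionless gate value; `hh_tau_n`: seconds.
#' @export
hh_n_inf <- function(v) {
  a <- hh_alpha_n(v)
  a / (a + hh_beta_n(v))
}

#' @rdname hh_n_inf
#' @export
hh_tau_n <- function(v) {
  1 / (hh_alpha_n(v) + hh_beta_n(v))
}

#' Time course of the n gate after a voltage jump
#'
#' Single-exponential relaxation
#' \deqn{n(t) = n_\infty(V_a) - (n_\infty(V_a) - n_\infty(V_b))
#'   e^{-t/\tau_n(V_a)}}
#' from the steady state at the pre-jump voltage to the one at the
#' post-jump voltage. This is the exact solution of
#' \eqn{dn/dt = \alpha_n(1-n) - \beta_n n} at fixed \eqn{V_a}.
#'
#' @param v_after post-jump voltage in volts.
#' @param v_before pre-jump voltage in volts.
#' @param t time(s) since the jump, seconds (>= 0).
#' @return Gate value(s) in (0,1).
#' @export
hh_n_of_t <- function(v_after, v_before, t) {
  if (any(t < 0)) stop("t must be non-negative")
  ninf <- hh_n_inf(v_after)
  ninf - (ninf - hh_n_inf(v_before)) * exp(-t / hh_tau_n(v_after))
}

#' Steady-state open probability of the potassium channel
#'
#' Four identical independent gates: \eqn{P_{open,K}(V) = n_\infty^4(V)}.
#'
#' @param v membrane voltage(s) in volts.
#' @return Probability in (0,1).
#' @export
hh_open_probability <- function(v) {
  hh_n_inf(v)^4
}

#' Potassium conductance after a voltage jump
#'
#' \eqn{g_K(V,t) = g_{K,0}\, n^4(V,t)}.
#'
#' @param hh an [hh_potassium()] object.
#' @param v_after,v_before voltages in volts.
#' @param t time(s) since the jump, seconds.
#' @return Conductance(s) in siemens.
#' @export
hh_conductance <- function(hh, v_after, v_before, t) {
  stopifnot(inherits(hh, "hh_potassium"))
  hh$g_max_S * hh_n_of_t(v_after, v_before, t)^4
}

#' Tabulate potassium and lipid-pore open probabilities on a voltage grid
#'
#' Side-by-side curves for visual comparison: the Hodgkin-Huxley
#' potassium-channel steady-state open probability and the lipid-pore open
#' probability for each supplied energetics parameterization. No
#' similarity statistic is computed -- the comparison is visual.
#'
#' @param v_grid voltages in volts (non-empty).
#' @param pe_list list of [pore_energetics()] objects (may be empty, in
#'   which case only the potassium column is returned).
#' @return A data.frame with `voltage_V`, `p_open_K`, and one
#'   `p_open_pore_<i>` column per energetics entry.
#' @export
compare_open_probabilities <- function(v_grid, pe_list = list()) {
  stopifnot(length(v_grid) >= 1)
  out <- data.frame(voltage_V = v_grid,
                    p_open_K = hh_open_probability(v_grid))
  for (i in seq_along(pe_list)) {
    out[[paste0("p_open_pore_", i)]] <-
      open_probability(pe_list[[i]], v_grid)
  }
  out
}

#' Reference table of potassium-gate quantities
#'
#' @param vmin_V,vmax_V,step_V grid limits and spacing in volts.
#' @return A data.frame of V, alpha_n, beta_n, n_inf, tau_n, P_open,K.
#' @export
hh_table <- function(vmin_V = -0.1, vmax_V = 0.05, step_V = 0.005) {
  v <- seq(vmin_V, vmax_V, by = step_V)
  data.frame(voltage_V = v,
             alpha_n_per_s = hh_alpha_n(v),
             beta_n_per_s = hh_beta_n(v),
             n_inf = hh_n_inf(v),
             tau_n_s = hh_tau_n(v),
             p_open_K = hh_open_probability(v))
}
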