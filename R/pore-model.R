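# Thermodynamic two-state pore model and small biophysical utilities.
# All quantities SI internally (V, A, S, F, s, K); pore energies are
# dimensionless multiples of kT with temperature carried explicitly.

#' Pore energetics of a voltage-gated lipid pore
#'
#' Parameter record for the quadratic free-energy model of pore opening.
#' The free-energy difference between the open and the closed state is
#' \deqn{\Delta\mu_0(V) = \Delta\mu(0) - \alpha\left[(V+V_0)^2 - V_0^2\right]}
#' in units of kT. The applied voltage stabilizes the open pore quadratically,
#' so \eqn{\Delta\mu_0} is maximal -- and the open probability minimal -- at
#' \eqn{V = -V_0}. The offset \eqn{V_0} arises from a spontaneous polarization
#' of the membrane (e.g. via curvature-induced flexoelectricity in a patch
#' pipette); a flat bilayer has \eqn{V_0 = 0} and a symmetric I-V relation.
#'
#' @param dmu0_kT free energy of a pore at \eqn{V = 0}, in kT (dimensionless).
#'   Positive values mean pores are mostly closed at zero voltage.
#' @param alpha_kT_per_V2 quadratic coefficient \eqn{\alpha} in kT/V^2.
#'   Must be positive (pores are stabilized symmetrically away from
#'   \eqn{-V_0}); zero is tolerated only for degenerate,
#'   voltage-independent fixtures.
#' @param offset_V voltage offset \eqn{V_0} in volts.
#' @return An object of class `"pore_energetics"`.
#' @examples
#' pe <- pore_energetics(dmu0_kT = 4, alpha_kT_per_V2 = 40, offset_V = 0.2)
#' open_probability(pe, 0.2)
#' @export
pore_energetics <- function(dmu0_kT, alpha_kT_per_V2, offset_V = 0) {
  stopifnot(is.numeric(dmu0_kT), length(dmu0_kT) == 1L, is.finite(dmu0_kT))
  stopifnot(is.numeric(alpha_kT_per_V2), length(alpha_kT_per_V2) == 1L,
            is.finite(alpha_kT_per_V2))
  if (alpha_kT_per_V2 < 0)
    stop("alpha_kT_per_V2 must be >= 0 (strictly positive except in degenerate fixtures)")
  stopifnot(is.numeric(offset_V), length(offset_V) == 1L, is.finite(offset_V))
  structure(list(dmu0_kT = dmu0_kT,
                 alpha_kT_per_V2 = alpha_kT_per_V2,
                 offset_V = offset_V),
            class = "pore_energetics")
}

#' @export
print.pore_energetics <- function(x, ...) {
  cat("Pore energetics: dmu(0) =", x$dmu0_kT, "kT, alpha =",
      x$alpha_kT_per_V2, "kT/V^2, V0 =", x$offset_V * 1e3, "mV\n")
  invisible(x)
}

#' Conductance parameters of the two-process conduction model
#'
#' Leak and pore conductances of a membrane: a voltage-independent leak
#' `g_leak_S` and `n_pores` identical pores of single-pore conductance
#' `g_single_S`, giving a total open-pore conductance
#' `g_pores_S = n_pores * g_single_S`.
#'
#' @param g_leak_S leak conductance in siemens.
#' @param g_pores_S total conductance of all pores when open, in siemens.
#'   Derived from `n_pores * g_single_S` when those are given.
#' @param g_single_S single-pore conductance in siemens.
#' @param n_pores non-negative integer pore count.
#' @return An object of class `"conductance_set"`.
#' @export
conductance_set <- function(g_leak_S = 0, g_pores_S = NULL,
                            g_single_S = NULL, n_pores = NULL) {
  stopifnot(is.numeric(g_leak_S), length(g_leak_S) == 1L, g_leak_S >= 0)
  if (!is.null(n_pores)) {
    stopifnot(n_pores >= 0, n_pores == round(n_pores))
    n_pores <- as.integer(n_pores)
  }
  if (is.null(g_pores_S)) {
    if (!is.null(g_single_S) && !is.null(n_pores)) {
      g_pores_S <- n_pores * g_single_S
    } else {
      g_pores_S <- 0
    }
  }
  stopifnot(g_pores_S >= 0)
  if (!is.null(g_single_S)) stopifnot(g_single_S >= 0)
  if (!is.null(g_single_S) && !is.null(n_pores) &&
      abs(g_pores_S - n_pores * g_single_S) >
        1e-12 * max(1, abs(g_pores_S))) {
    stop("g_pores_S must equal n_pores * g_single_S when both are specified")
  }
  structure(list(g_leak_S = g_leak_S, g_pores_S = g_pores_S,
                 g_single_S = g_single_S, n_pores = n_pores),
            class = "conductance_set")
}

#' Recording environment: temperature and ionic conditions
#'
#' Carries the absolute temperature and the Nernst potential \eqn{E_0} of
#' the conducted ion. When concentrations are supplied, \eqn{E_0} is
#' computed as \eqn{(RT/zF)\,\ln(c_{out}/c_{in})}; with identical buffer on
#' both sides (the usual case here) \eqn{E_0 = 0}.
#'
#' @param temperature_K absolute temperature (> 0).
#' @param nernst_V Nernst potential in volts; computed from concentrations
#'   when they are given.
#' @param ion_valence ion charge number z.
#' @param conc_out,conc_in ion concentrations outside/inside (same units).
#' @return An object of class `"recording_env"`.
#' @export
recording_env <- function(temperature_K = 297.85, nernst_V = 0,
                          ion_valence = 1, conc_out = NULL, conc_in = NULL) {
  stopifnot(temperature_K > 0)
  if (!is.null(conc_out) && !is.null(conc_in)) {
    nernst_V <- nernst_potential(conc_out, conc_in, ion_valence, temperature_K)
  }
  structure(list(temperature_K = temperature_K, nernst_V = nernst_V,
                 ion_valence = ion_valence,
                 conc_out = conc_out, conc_in = conc_in),
            class = "recording_env")
}

#' Membrane capacitor with spontaneous polarization
#'
#' The stored charge is \eqn{q = C_m V + A P_0}: a conventional capacitive
#' term plus an offset charge from the areal spontaneous polarization
#' \eqn{P_0}. Equivalently \eqn{q = C_m^*(V) V} with the effective
#' capacitance \eqn{C_m^* = C_m (1 + V_0/V)}.
#'
#' @param capacitance_F membrane capacitance \eqn{C_m} (>= 0).
#' @param area_m2 membrane area (>= 0).
#' @param polarization_C_per_m2 spontaneous polarization \eqn{P_0} such that
#'   the offset charge is `area_m2 * polarization_C_per_m2`.
#' @return An object of class `"membrane_capacitor"`.
#' @export
membrane_capacitor <- function(capacitance_F, area_m2 = 0,
                               polarization_C_per_m2 = 0) {
  stopifnot(capacitance_F >= 0, area_m2 >= 0)
  structure(list(capacitance_F = capacitance_F, area_m2 = area_m2,
                 polarization_C_per_m2 = polarization_C_per_m2),
            class = "membrane_capacitor")
}

#' Pipette access circuit
#'
#' Series resistance and capacitance of the recording pipette. Carried for
#' completeness of the equivalent circuit; the pipette contributes
#' negligibly to the observed currents and is not used in fitting.
#'
#' @param series_resistance_Ohm series resistance (>= 0).
#' @param pipette_capacitance_F pipette wall capacitance (>= 0).
#' @return An object of class `"pipette_circuit"`.
#' @export
pipette_circuit <- function(series_resistance_Ohm = 0,
                            pipette_capacitance_F = 0) {
  stopifnot(series_resistance_Ohm >= 0, pipette_capacitance_F >= 0)
  structure(list(series_resistance_Ohm = series_resistance_Ohm,
                 pipette_capacitance_F = pipette_capacitance_F),
            class = "pipette_circuit")
}

#' Pore free energy at an applied voltage
#'
#' Evaluates \eqn{\Delta\mu_0(V) = \Delta\mu(0) -
#' \alpha[(V+V_0)^2 - V_0^2]} in kT. The value equals `dmu0_kT` at
#' \eqn{V = 0} and at \eqn{V = -2V_0} and is maximal at \eqn{V = -V_0}.
#'
#' @param pe a [pore_energetics()] object.
#' @param v applied voltage(s) in volts.
#' @return Free energy difference(s) open minus closed, in kT.
#' @export
pore_free_energy <- function(pe, v) {
  stopifnot(inherits(pe, "pore_energetics"), is.numeric(v))
  pe$dmu0_kT - pe$alpha_kT_per_V2 * ((v + pe$offset_V)^2 - pe$offset_V^2)
}

#' Equilibrium open probability of a pore
#'
#' \eqn{P_{open} = K/(1+K)} with \eqn{K = \exp(-\Delta\mu_0/kT)}, evaluated
#' through the numerically stable logistic form so that large
#' \eqn{|\Delta\mu_0|} cannot overflow. \eqn{P_{open} + P_{closed} = 1};
#' the minimum of \eqn{P_{open}} lies at \eqn{V = -V_0} and the curve is
#' symmetric about it.
#'
#' @inheritParams pore_free_energy
#' @return Open probability in (0, 1), same length as `v`.
#' @export
open_probability <- function(pe, v) {
  stats::plogis(-pore_free_energy(pe, v))
}

#' Steady-state membrane current of the two-process model
#'
#' \eqn{I(V) = (g_L + g_p P_{open}(V)) (V - E_0)}: a voltage-independent
#' leak in parallel with voltage-gated pores, driven by the displacement
#' from the Nernst potential.
#'
#' @param cs a [conductance_set()].
#' @param pe a [pore_energetics()].
#' @param env a [recording_env()] (supplies \eqn{E_0}).
#' @param v applied voltage(s) in volts.
#' @return Current(s) in amperes.
#' @export
steady_state_current <- function(cs, pe, env, v) {
  stopifnot(inherits(cs, "conductance_set"), inherits(env, "recording_env"))
  (cs$g_leak_S + cs$g_pores_S * open_probability(pe, v)) * (v - env$nernst_V)
}

#' Nernst equilibrium potential
#'
#' \eqn{E_0 = (RT/zF)\ln(c_{out}/c_{in})} for an ion of valence z.
#'
#' @param conc_out,conc_in concentrations (> 0, same units).
#' @param z ion valence (non-zero).
#' @param temperature_K absolute temperature (> 0).
#' @return Potential in volts.
#' @examples
#' nernst_potential(10, 1, z = 1, temperature_K = 297) # ~58.9 mV
#' @export
nernst_potential <- function(conc_out, conc_in, z = 1, temperature_K = 297.85) {
  if (any(conc_out <= 0) || any(conc_in <= 0))
    stop("concentrations must be positive")
  if (any(z == 0)) stop("ion valence must be non-zero")
  if (temperature_K <= 0) stop("temperature must be positive")
  R <- 8.31446261815324   # J/(mol K)
  F <- 96485.33212331001  # C/mol
  (R * temperature_K) / (z * F) * log(conc_out / conc_in)
}

#' Convert between resistance and conductance
#'
#' @param g conductance in siemens (> 0).
#' @return Resistance in ohms, `1/g`.
#' @export
resistance_from_conductance <- function(g) {
  if (any(g <= 0)) stop("conductance must be positive")
  1 / g
}

#' @rdname resistance_from_conductance
#' @param r resistance in ohms (> 0).
#' @export
conductance_from_resistance <- function(r) {
  if (any(r <= 0)) stop("resistance must be positive")
  1 / r
}

#' Single-channel conductance from a current step
#'
#' The conductance of one open pore given the quantized current step it
#' produces and the driving force: `step_current_A / (v - e0)`.
#'
#' @param step_current_A amplitude of the conduction step in amperes.
#' @param v applied voltage in volts.
#' @param e0 Nernst potential in volts.
#' @return Conductance in siemens.
#' @examples
#' single_channel_conductance(13e-12, 0.190) # ~68 pS
#' @export
single_channel_conductance <- function(step_current_A, v, e0 = 0) {
  if (any(v == e0)) stop("driving force v - e0 must be non-zero")
  step_current_A / (v - e0)
}

#' Hydrostatic pressure at depth
#'
#' \eqn{p = \rho g h}; the pressure difference across a membrane patch whose
#' pipette tip sits `depth_m` below the bath surface.
#'
#' @param depth_m depth below the surface in metres (>= 0).
#' @param density_kg_m3 fluid density, default water.
#' @param gravity_m_s2 gravitational acceleration.
#' @return Pressure in pascal.
#' @export
hydrostatic_pressure <- function(depth_m, density_kg_m3 = 1000,
                                 gravity_m_s2 = 9.81) {
  if (any(depth_m < 0)) stop("depth must be non-negative")
  density_kg_m3 * gravity_m_s2 * depth_m
}

#' Maximum curvature of a membrane spanning an aperture
#'
#' The most strongly curved shape a membrane across a circular aperture can
#' take is a hemispherical cap whose radius equals the aperture radius, so
#' the maximum attainable curvature is `2/diameter`. A ~1 um patch-pipette
#' tip admits curvature 1/(500 nm); a ~100 um bilayer aperture admits 100x
#' less, which is why flat bilayers show no polarization offset.
#'
#' @param aperture_diameter_m aperture diameter in metres (> 0).
#' @return Curvature in 1/m.
#' @export
max_aperture_curvature <- function(aperture_diameter_m) {
  if (any(aperture_diameter_m <= 0)) stop("aperture diameter must be positive")
  2 / aperture_diameter_m
}

#' Charge on a spontaneously polarized membrane capacitor
#'
#' \eqn{q = C_m V + A P_0}.
#'
#' @param mc a [membrane_capacitor()].
#' @param v voltage(s) in volts.
#' @return Charge in coulombs.
#' @export
membrane_charge <- function(mc, v) {
  stopifnot(inherits(mc, "membrane_capacitor"))
  mc$capacitance_F * v + mc$area_m2 * mc$polarization_C_per_m2
}

#' Effective capacitance including the polarization offset
#'
#' Writing \eqn{q = C_m^* V} gives \eqn{C_m^* = C_m (1 + V_0/V)}; undefined
#' at \eqn{V = 0}.
#'
#' @param mc a [membrane_capacitor()].
#' @param v0_V polarization offset voltage in volts.
#' @param v voltage(s) in volts, non-zero.
#' @return Effective capacitance in farad.
#' @export
effective_capacitance <- function(mc, v0_V, v) {
  stopifnot(inherits(mc, "membrane_capacitor"))
  if (any(v == 0)) stop("effective capacitance is undefined at v = 0")
  mc$capacitance_F * (1 + v0_V / v)
}
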