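# shared fixtures: the rectified patch regime and the symmetric BLM regime
# used throughout the suite

patch_energetics <- function() pore_energetics(4, 40, 0.2)
blm_energetics <- function() pore_energetics(4, 100, 0)

patch_conductances <- function()
  conductance_set(g_leak_S = 0.37e-9, g_pores_S = 1.5e-9)

# independent composition oracle for the steady-state current: evaluates
# the free energy, Boltzmann factor and conduction law term by term,
# without the package's plogis shortcut
oracle_current <- function(g_leak, g_pores, dmu0, alpha, v0, e0, v) {
  dmu <- dmu0 - alpha * ((v + v0)^2 - v0^2)
  K <- exp(-dmu)
  p <- K / (1 + K)
  (g_leak + g_pores * p) * (v - e0)
}

# mean-gating (ensemble) noisy series at the standard protocol
simulate_patch_series <- function(seed, cs = patch_conductances(),
                                  pe = patch_energetics(),
                                  noise = noise_model()) {
  simulate_trace(build_protocol(), cs, pe, recording_env(),
                 gating_kinetics(), transient_params(), noise,
                 seed = seed, gating = "mean")
}

# analytic standard error of the time-averaged open fraction of n
# independent two-state pores observed for duration_s (stationary
# Ornstein-Uhlenbeck-type variance of a Markov dichotomous process)
occupancy_se <- function(p, k_open, k_close, duration_s, n_pores) {
  tau_c <- 1 / (k_open + k_close)
  sqrt(2 * p * (1 - p) * tau_c / (duration_s * n_pores))
}
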