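---
title: "Two-process conduction in lipid membranes: model, simulator and fitting methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-process conduction in lipid membranes: model, simulator and fitting methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreiv)
```

## The physical picture

Protein-free lipid bilayers near their order–disorder (melting)
transition are not inert insulators. Thermal fluctuations open transient
aqueous pores that carry quantized currents, with single-event
conductances (tens of pS), open lifetimes (10–100 ms) and voltage
dependence all in the range reported for protein channels. `poreiv`
models the electrical behaviour of such membranes as the sum of two
processes:

* a **leak**: a voltage-independent conductance $g_L$ attributed to the
  membrane seal and diffuse defects, present in every recording and
  never resolved into discrete events;
* **voltage-gated pores**: $N$ identical two-state pores of single-pore
  conductance $g_{pore}$, total $g_p = N\,g_{pore}$, whose open
  probability follows from a free energy quadratic in voltage.

The steady-state current at applied voltage $V$ is

$$ I(V) = \bigl(g_L + g_p P_{open}(V)\bigr)\,(V - E_0), $$

with $E_0$ the Nernst potential of the conducted ion
($E_0 = (RT/zF)\ln(c_{out}/c_{in})$, zero for identical buffers on the
two sides, the usual situation here).

## Pore energetics and the sign convention

The open–closed free-energy difference of one pore is taken quadratic in
voltage with an offset:

$$ \Delta\mu(V) \;=\; \Delta\mu(0) \;-\; \alpha\left[(V+V_0)^2 - V_0^2\right],
\qquad \alpha > 0, $$

in units of $kT$, and the open probability is the Boltzmann weight
$P_{open} = K/(1+K)$ with $K = e^{-\Delta\mu(V)}$.

The sign of the quadratic term deserves a remark, because both
conventions appear in the electroporation literature depending on
whether the quadratic coefficient is written as a stabilization or a
destabilization energy. The physics pins it down: an applied field
lowers the free energy of an aqueous pore (dielectric energy gain of
replacing lipid by water), so conduction **grows** away from the
symmetry point. With the convention above, $\Delta\mu$ is maximal — and
$P_{open}$ minimal — at $V = -V_0$, and the open probability rises
symmetrically on both sides of it. This is the behaviour the package is
built around: outward-rectified patch recordings are described by
$V_0 \approx +0.2$ V (pores open only toward positive voltages within a
±200 mV protocol), while flat bilayers have $V_0 = 0$ and open pores at
both high positive and high negative voltage. Writing the quadratic
term with the opposite sign while keeping $K = e^{-\Delta\mu}$ would put
the *maximum* of $P_{open}$ at $-V_0$ and cannot produce this phenomenology
with $\alpha > 0$; the package therefore fixes the convention once, here,
and uses it consistently.

The offset $V_0$ itself is treated as a phenomenological parameter. Its
plausible physical origin is a spontaneous membrane polarization, e.g.
flexoelectric polarization of the curved patch spanning a ~1 µm pipette
tip. The geometric utility `max_aperture_curvature()` (curvature of a
hemispherical cap, $2/d$) quantifies why a ~100 µm bilayer aperture
admits ~100-fold less curvature, hence effectively no offset; no
quantitative polarization–curvature theory is implemented.

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `dmu0_kT` | pore free energy at 0 V (kT) | 4 | pores mostly closed at rest ($P_{open}(0)\approx 0.02$) |
| `alpha_kT_per_V2` | field stabilization (kT/V²) | 40 | gives $P_{open}(+200\,\mathrm{mV}) \approx 0.7$ at $V_0 = 0.2$ V, the observed rectified regime |
| `offset_V` | polarization offset $V_0$ (V) | 0.2 | patch-regime scale; 0 in bilayer mode |
| `g_leak_S` | leak conductance | 0.37 nS | linear-recording scale (≈ 2.7 GΩ seal) |
| `g_pores_S` | total open-pore conductance | 1.5 nS | rectified-recording scale |
| `g_single_S` | single-pore conductance | 30–78 pS | quantized-step scale (13 pA at 190 mV ≈ 68 pS) |
| `mean_open_lifetime_s` | mean open dwell | 30 ms | middle of the observed 10–100 ms range |
| `tau_fast_s`, `tau_slow_s` | transient time constants | 258 µs, 1.74 ms | capacitor charging (set by the recording chain) and membrane structural relaxation |
| `current_noise_sd_A` | white noise per 10 kHz sample | 2 pA | recording-noise scale |
| `filter_cutoff_Hz` | causal low-pass | 2 kHz | standard hardware filter |

Voltages are SI volts internally (reports print mV/pS), energies are
dimensionless multiples of kT with the temperature carried explicitly in
`recording_env()` (default 297.85 K), which avoids Boltzmann-constant
plumbing while keeping $K = e^{-\Delta\mu/kT}$ exact.

## The synthetic-data generator

`simulate_trace()` emulates the standard step protocol: +200 to −200 mV
in −25 mV steps (17 levels), 3.1 s per step preceded by a 50 ms holding
segment, 10 kHz sampling, 2 kHz causal low-pass. Each per-level trace
contains the decay of the return jump at its start and the step jump at
50 ms, so both jump directions are available to the relaxation fitter.

**Gating.** The equilibrium model fixes only $P_{open}(V)$; dynamics
require a choice. The generator uses a continuous-time two-state Markov
chain per pore with a voltage-independent closing rate
$k_{close} = 1/\tau_{open}$ — single-pore conductance and open lifetime
do not detectably depend on voltage — and puts all voltage dependence in
the opening rate $k_{open}(V) = k_{close}K(V)$, so the stationary law is
exactly $P_{open}(V)$. Dwells are sampled exponentially in continuous
time and then binned onto the sampling grid; initial states are drawn
from equilibrium at the pre-jump voltage, so pore-number relaxation after
a jump is reproduced. A deterministic `gating = "mean"` mode replaces the
pore count by its expectation $N P_{open}(V)$; it is the appropriate mode
when the object of interest is the ensemble I-V relation rather than
event statistics (a 16-point series carries the gating fluctuations of
at most a few tens of pores, which dominate the scatter of fitted
parameters — see identifiability below).

**Transients.** Jump transients are biexponential,
$A_0 e^{-t/\tau_0} + A_m e^{-t/\tau_m}$, with amplitudes either
proportional to the jump size (default: $A_0 = C_m \Delta V/\tau_0$ with
$C_m = 100$ pF, ideal-capacitor charging) or computed exactly from a
structural `transient_decomposition()` (changes in capacitance,
polarization charge and conductance between the steady states before and
after the jump).

**Noise and filter.** White Gaussian noise is added per raw sample and
the sum passed through a forward-only (causal) digital Butterworth
low-pass, the digital stand-in for the causal hardware filter; the
filter has unit DC gain, so steady-state means are preserved. An
optional linear baseline drift is off by default.

**What the generator does not emulate**: membrane rupture,
non-equilibrating high-voltage transients occasionally seen on the first
jump of real series, pipette series-resistance and capacitance charging
(negligible against GΩ membranes), 1/f and line noise, and any
correlation between pore availability and recording history (real
membranes alternate between linear and rectified behaviour between
series; the simulator exposes pore count $N = 0$ vs $N > 0$ as that
switch without a mechanism). Passing tests on synthetic traces therefore
demonstrates the correctness of the analysis chain under the stated
model, not the model's adequacy for any particular real membrane.

## Steady-state extraction and fitting

`extract_iv()` averages the settled tail of each step (default 1.5–3 s
after onset, i.e. the second half of a standard step). The first level
of a series can be flagged as an outlier (`discard_first`), reflecting
the common observation that the first jump has not equilibrated.
`correct_offset()` subtracts the mean of the settled second half of the
holding segment; note that with a 50 ms holding segment this reference
carries ~0.1 pA of averaging noise, which matters for the offset
parameter (below) when no real amplifier offset is present.

`fit_iv()` performs weighted nonlinear least squares on the per-level
means (weights $1/\mathrm{SE}^2$; fitting all window samples instead
yields the same estimator, at far higher cost). Scenarios: pores only
($g_L = 0$), fixed leak (taken from a linear recording of the same
membrane), free leak, and linear. Numerical choices:

* **Reparameterization.** When $P_{open} \ll 1$ across the window, $g_p$
  and $e^{-\Delta\mu(0)}$ are nearly perfectly degenerate. The fitter
  therefore uses $(\log g_p,\; V_0,\; \mathrm{logit}\,p_{min},\;
  \log\alpha\,[,\log g_L])$, with $p_{min} = P_{open}(-V_0)$ the minimum
  open probability; $\Delta\mu(0)$ is derived afterwards. Positivity of
  conductances and $\alpha$, and $p_{min}\in(0,1)$, are enforced by the
  transforms rather than by constraints.
* **Stable logistic.** $P_{open}$ is computed as
  `plogis(-dmu)`; no overflow for arbitrarily large $|\Delta\mu|$.
* **Multi-start.** Levenberg–Marquardt from every $V_0$ start in
  $\{-0.3, -0.25, \ldots, +0.3\}$ V; best residual sum of squares wins,
  ties (within $10^{-9}$ relative) broken toward smaller $|V_0|$.
  Convergence: relative tolerances $10^{-10}$, at most 500 iterations
  per start; failure of every start raises a fit-failure error.
* **Diagnostics.** The object reports $p_{min}$ and its location $-V_0$,
  delta-method standard errors on the natural scale, and standard
  `print`/`summary`/`coef`/`predict`/`residuals`/`plot`/`simulate`
  methods.

**Identifiability of the offset.** Writing the logit of $P_{open}$ as a
quadratic in $V$ shows $V_0$ is the ratio of its linear to quadratic
coefficient over the voltage window where pore conduction is measurable.
For a rectified profile that window is narrow (roughly 0 to +200 mV), so
$V_0$ sits on a flat likelihood ridge: per-level errors of even ~0.1 pA
move the global optimum by tens of mV, and occasional excursions of
~100 mV occur at realistic noise. Symmetric (bilayer) profiles constrain
$V_0$ far better because both branches carry pore current. Consequences
adopted here: ensemble-mode simulations are used when demonstrating
parameter recovery; repeated series are fitted and their per-series
offsets summarized by the median when a single headline $V_0$ is wanted
(mirroring the experimental practice of averaging $V_0$ over repeated
recordings); and offset correction is skipped when no offset is present
to correct, since its reference noise feeds the ridge.

`detect_negative_slope()` flags centred difference quotients below
$-2\times$ their propagated standard error — regions with
$dI/dV < 0$, impossible for any voltage-independent conductance and a
direct signature of gating on the negative branch.
`compare_depths()` reports per-condition mean ± sd of $V_0$ and pairwise
percent changes $100(b-a)/a$ of $g_L$ and $g_p$, the convention used for
pressure-gradient (pipette-depth) comparisons.

## Relaxation fitting

`fit_relaxation()` fits
$I(t) = g_a V_a + A_0 e^{-t/\tau_0} + A_m e^{-t/\tau_m}$ to the post-jump
segment of every trace, dropping the first 100 µs (the resolution of the
recording). Both time constants are shared across all jumps of a series
— both reflect membrane/recording-chain properties, not the jump size —
via a two-stage scheme: a Nelder–Mead search over
$(\log\tau_0, \log(\tau_m/\tau_0 - 1))$ (the parameterization enforces
$\tau_0 < \tau_m$; relative tolerance $10^{-12}$, restart from the
solution to guard against simplex collapse) wrapped around exact linear
least squares for the three amplitudes of each jump. $\tau_0$ may be
fixed (it is typically pinned by the recording filter), leaving a 1-D
search for $\tau_m$. The identity
$\lim_{t\to\infty} I = g_a V_a$ ties the fitted plateau to the
steady-state I-V point of the same level.

The structural decomposition
$(\Delta C_m, \Delta(AP_0), \Delta g)$ is **not** identifiable from the
fitted $(A_0, A_m, \mathrm{plateau})$ of a single jump — three observed
numbers cannot split into four structural ones — so the package fits
lumped amplitudes only and offers the decomposition strictly as a
forward model. `amplitude_voltage_analysis()` classifies each amplitude
as `linear` or `rectified` by correlating its residuals from a
straight-line fit $A = aV$ with the nonlinearity of the measured I-V
profile (threshold correlation 0.6; amplitudes with relative residual
power below $10^{-6}$ are linear outright). One fast-component caveat:
a causal 2 kHz filter smears the first ~1 ms of a jump, so recovering a
~258 µs time constant from filtered traces is ill-posed; wide-band
(unfiltered) simulations are used when the fast constant itself is the
quantity of interest, and a fixed $\tau_0$ is recommended on filtered
data.

## Event idealization

`idealize()` standardizes what is usually read by eye:

1. candidate conduction levels are the peaks of the amplitude density
   (bandwidth floored at 1% of the amplitude range so near-noiseless
   quantized traces keep resolved point masses; peaks closer than two
   bandwidths merge);
2. the closed level is the peak nearest zero along the driving-force
   direction, and the step size is the median nearest-level gap
   (identical pores ⇒ equally spaced levels);
3. samples are assigned by half-amplitude threshold crossing with
   hysteresis (enter a level 0.5 steps above it, leave at 0.35), which
   rejects noise chatter around a single threshold;
4. runs shorter than 2 ms (≈ 4 samples at 2 kHz bandwidth, the shortest
   event the filter can represent) are merged into their predecessor.

A unimodal amplitude distribution returns an empty event list with one
level — no channels is a result, not an error. `baseline_correct()`
removes slow drift by a Theil–Sen line through per-window lower-envelope
quantiles (robust to windows in which the channel never closes), anchored
at the trace start so drift-free traces pass through unchanged. Dead-time
censoring biases dwell means upward by about the 2 ms cutoff
(memorylessness of exponential dwells); the dwell statistics report raw
means and counts so users can apply the correction appropriate to their
cutoff. `empirical_open_probability()` reports both the fraction of time
at any open level and the per-pore time-averaged open fraction
(time-averaged level index over pore count); the latter is the quantity
directly comparable with `open_probability()`. No hidden-Markov
idealization, sub-conductance states or multi-amplitude mixtures are
attempted.

## Potassium-gate reference

`hh_alpha_n()`/`hh_beta_n()` implement the classical potassium-gate rate
functions (s⁻¹, voltages in volts, resting potential near −65 mV), with
the removable singularity of $\alpha_n$ at −55 mV evaluated by series
expansion within $10^{-7}$ V of the singular point. $n_\infty$, $\tau_n$,
the post-jump gate solution $n(t)$ (verified against direct ODE
integration to $10^{-8}$), $P_{open,K} = n_\infty^4$ and
$g_K = g_{K,0} n^4$ follow. `compare_open_probabilities()` tabulates the
potassium curve next to any set of lipid-pore parameterizations on a
common grid; the comparison is deliberately visual — no similarity
statistic is asserted, because the claim it supports is qualitative
(lipid pores can mimic potassium-channel gating), not metric.

## Pipeline, formats, reproducibility

Traces are stored as tab-separated text with a commented header whose
JSON metadata line fully reconstructs the simulation (format tag,
declared sample count, every generator parameter and the seed); reading
back is value-exact, and malformed or truncated files fail with the
offending line number. `run_config()` validates nested parameter records
against the module schemas and rejects unknown keys; `config_hash()`
(MD5 of the canonical JSON) changes whenever any parameter does.
`run_pipeline()` chains simulate → offset-correct → extract → fit →
relaxation → idealize → reference table, aborts with the stage name on
failure, and stamps outputs with hash and seed: identical configurations
give byte-identical tables. One master seed derives per-level substreams
deterministically, so any single trace can be regenerated alone. The
exported functions are the package's interface; there is no separate
shell tool beyond `scripts/acceptance.R`.

## Problem sizes and test design

The test suite exercises the full chain at deliberately modest sizes:
17-level series at 10 kHz (≈ 0.5 M samples per series), ten-seed
parameter-recovery sweeps, 20-pore × 20 s stationary-occupancy runs per
level, and single-channel recordings of 5–40 s. These sizes put the
Monte-Carlo standard errors comfortably below the assertion tolerances
(statistical assertions use three standard errors of the relevant
estimator, computed analytically from the dichotomous-process
autocorrelation time) while keeping the whole suite under a minute.

## Known limitations

* $V_0$ from a single rectified 16-point profile is soft (see
  identifiability); report it with its uncertainty or over repeated
  series.
* The fitted $(\Delta\mu(0), \alpha)$ pair is well determined only when
  the window samples both low and high open probability; otherwise use
  the $p_{min}$ parameterization's diagnostics rather than quoting
  $\Delta\mu(0)$ alone.
* The idealizer assumes equally spaced levels (identical pores) and a
  single dominant step size per trace.
* The relaxation model assumes a single slow structural relaxation; real
  membranes near their transition can show stretched or multi-modal
  relaxation.
* Absolute membrane capacitance is not estimable from these fits (the
  fast amplitude conflates membrane and recording-chain charging).
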