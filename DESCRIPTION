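Package: poreiv
Title: Voltage-Gated Lipid Pore Conductance Analysis for Patch-Clamp and
    Bilayer Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of current-voltage relations and current transients of
    protein-free lipid membranes under voltage clamp. Implements a two-state
    thermodynamic model of voltage-gated lipid pores with a spontaneous
    polarization offset, steady-state I-V fitting with separate leak and pore
    conduction, biexponential relaxation analysis of post-jump transients with
    relaxation times shared across jumps, idealization of quantized channel
    events with dwell-time statistics, and the Hodgkin-Huxley potassium gate
    as a reference. A built-in stochastic simulator generates voltage-clamp
    traces under the standard step protocol in both patch-pipette (rectified)
    and black-lipid-membrane (symmetric) regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
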