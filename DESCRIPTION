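Package: polaritylab
Title: Simulation and Non-Autonomous Analysis of Membrane Cell-Polarity Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates reaction-diffusion models of cell polarization (wave-pinning
    and its critically organized SubPB variant, local excitation-global inhibition,
    and a Turing-like mass-conserved activator) on a discretized circular membrane,
    deterministically and with additive noise. Provides a two-bin projection of the
    membrane for phase-plane work, numerical bifurcation continuation with
    pitchfork/saddle-node/transcritical detection, local perturbation analysis,
    quasi-potential landscapes from the stationary Fokker-Planck equation with
    Gaussian-curvature classification of asymptotic versus transient phase-space
    regions, and a standardized suite of polarization metrics (activation
    thresholds, polarization and re-polarization times, amplification, signal
    integration) for comparing how the mechanisms respond to spatial-temporal
    chemoattractant signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
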