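Package: memhr
Title: Simulation and Dynamics Analysis of a Memristive Hindmarsh-Rose
    Neuron under Multi-Frequency Forcing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a three-variable Hindmarsh-Rose neuron model in which
    the slow adaptation variable is replaced by magnetic flux through a
    flux-controlled memristor, driven by one or two sinusoidal current
    sources.  Provides the vector field and Jacobian, closed-form (Cardano)
    equilibrium solutions of the instantaneous cubic with stability
    classification, adaptive Runge-Kutta integration of the non-autonomous
    system, Lyapunov spectra by tangent-space QR reorthonormalization (with
    a two-trajectory Benettin cross-check), spike/burst detection and
    firing-pattern classification, bifurcation and coexistence parameter
    sweeps, multistability detection and elimination-threshold estimation,
    and a mapping between dimensionless model parameters and analog-circuit
    component values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
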