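Package: vibronic
Title: Linear Vibronic Coupling Models, Quantum Wavepacket Dynamics and
    Nonadiabatic Absorption Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for nonadiabatic vibronic spectroscopy and ultrafast
    excited-state dynamics of semi-rigid molecules such as the DNA/RNA
    nucleobases. Builds linear vibronic coupling (LVC) Hamiltonians of
    multiple coupled diabatic electronic states in dimensionless normal
    coordinates, parameterises them from adiabatic-state scans by
    maximum-overlap (orthogonal Procrustes) diabatization, propagates
    vibronic wavepackets exactly in a truncated harmonic-oscillator product
    basis with a short-iterative Lanczos integrator, and converts damped
    autocorrelation functions into absorption spectra at zero Kelvin.
    Includes diabatic population analysis with mono-exponential decay fits,
    a closed-form displaced-oscillator (vertical gradient) reference
    propagator, and seeded synthetic fixtures so the whole pipeline is
    testable without any electronic-structure calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
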