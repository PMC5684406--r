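Package: excitondelay
Title: Time-Delayed Coherent Feedback Dynamics of an Excitonic Dimer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the non-Markovian dynamics of a Frenkel-exciton dimer
    (reduced to an effective two-level system) coupled to a phonon bath at two
    spatial points, forming a coherent feedback loop with time delay. Provides
    the feedback spectral density and its delta-comb dissipation kernel, a
    method-of-steps Runge-Kutta solver for the resulting delay differential
    equation together with an exact piecewise closed form, Lambert-W
    characteristic roots, a Volterra memory-kernel engine for general
    single-excitation site systems, observables (populations, coherence,
    steady-state trapping limits, beating metrics), parameter sweeps, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
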