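Package: phasic
Title: Noise-Enhanced Coding in Phasic Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and semi-analytic theory of noise-enhanced coding in
    phasic (Class III) neurons. Provides a stochastic FitzHugh-Nagumo
    simulator with a voltage-dependent recovery timescale, spike-train
    statistics (firing rate, phase density, vector strength, spike-triggered
    average, power spectra), deterministic phase-plane analysis (separatrix
    and distance-to-threshold traces), a reduced two-barrier hazard/renewal
    theory solved in the Fourier domain for interspike-interval and
    spike-phase densities, and an exact thinning Monte Carlo simulator of the
    reduced point process for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
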