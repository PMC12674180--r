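Package: pulsetrack
Title: Continuous Scatterer Tracking for High-Speed Plane-Wave Ultrasound
    Flow Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate high-speed plane-wave ultrasound of complex
    pulsatile blood flow without slow-time discontinuities. A gridded
    velocity-field time series (from a computational flow model or the
    built-in analytic generators) drives Lagrangian advection of
    blood-mimicking point scatterers; refresh zones at flow ports and a
    stagnation threshold at the flow boundary keep the local scatterer
    concentration stable over an arbitrary number of cardiac cycles. A
    point-target plane-wave simulator, delay-and-sum beamformer, lag-one
    autocorrelation colour Doppler, and multi-angle least-squares vector
    flow close the loop so transmit schemes and velocity estimators can be
    exercised on realistic synthetic flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
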