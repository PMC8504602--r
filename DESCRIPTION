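Package: dempqa
Title: Angular-Response Modelling and Composite-Dose QA for 2D Ion-Chamber Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the angular dependence of a 2D ionization-chamber array's
    response as a dynamical displacement of its effective measurement plane
    (a per-angle depth offset plus an effective anode density), calibrates the
    model from per-angle measurements by bounded Levenberg-Marquardt least
    squares, applies it to angularly corrected composite planar-dose
    calculation for fixed-gantry IMRT QA, and evaluates agreement with
    gamma-index criteria. Includes a simplified divergent-beam photon dose
    engine with Siddon-style radiological path lengths and a virtual detector
    simulator so the whole pipeline runs without a linac.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
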