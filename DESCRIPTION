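Package: cardioinverse
Title: Identification of Ion-Channel Drug Effects from Cardiomyocyte
    Voltage and Calcium Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A configurable action-potential and calcium-transient base
    model of human cardiomyocytes (membrane currents, five intracellular
    calcium compartments, availability-limited ryanodine-receptor release),
    with IC50-based dose-response channel block, a continuation-based
    multi-start Nelder-Mead inversion that jointly fits channel-density
    adjustment factors and drug potencies across a dose-escalation series,
    an SVD-based identifiability analysis of the model currents, and a
    maturation map translating drug effects identified in stem-cell-derived
    cardiomyocytes to an adult-cardiomyocyte parameterization.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
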