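Package: lsrswitch
Title: Kinetic Modelling and Knockout Analysis of the E. coli lsr Quorum-Sensing Circuit
Version: 0.1.0
Authors@R:
    person("lsrswitch", "developers", email = "lsrswitch@example.org",
           role = c("aut", "cre"))
Description: Ordinary-differential-equation models of autoinducer-2 (AI-2)
    uptake and lsr-operon regulation in luxS-null Escherichia coli. Simulates
    three nested network topologies (with and without a second lsr-encoded
    repressor and its AI-2-P sequestration), applies in-silico knockouts of
    the lsr operon, lsrR and lsrK, fits kinetic parameters to Miller-unit
    dose-response time courses by Hooke-Jeeves direct search with
    Latin-hypercube multistart, discriminates the competing topologies by
    joint least-squares fit quality and qualitative dose-response signatures,
    and generates calibrated synthetic beta-galactosidase assay datasets.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
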