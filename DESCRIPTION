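Package: fluctrate
Title: Rate Coding and Plasticity from Membrane-Potential Fluctuations in
    Balanced Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a balanced-input leaky
    integrate-and-fire neuron (Stein's model and its Ornstein-Uhlenbeck
    diffusion limit), maximum-likelihood firing-rate estimators from spike
    trains and from sampled membrane-potential traces with their Fisher
    information, and minimum-variance spike-dependent (SDP) and
    voltage-dependent (VDP) realizations of rate-based plasticity rules,
    instantiated for the BCM rule with a sliding threshold.  Includes the
    feed-forward input-selectivity learning experiment comparing SDP and VDP
    at short stimulus durations, CSV import/export of traces and spike
    trains, and reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
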