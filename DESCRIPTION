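Package: addbench
Title: Whole-Brain Activity-Dependent Degeneration Model and Functional
    Connectivity Biomarker Benchmark
Version: 0.1.0
Authors@R:
    person("addbench", "developers", email = "addbench@example.org",
           role = c("aut", "cre"))
Description: Simulates a whole-brain network of coupled excitatory/inhibitory
    neural masses on a structural connectome, with an activity-dependent
    degeneration (ADD) rule that converts excessive excitatory firing into
    progressive multiplicative synaptic weakening, emulating early
    Alzheimer's-disease pathophysiology (spectral slowing, network
    hyperexcitability, rising excitation/inhibition balance). On top of the
    simulator it provides a biomarker benchmark comparing functional
    connectivity measures (amplitude envelope correlation with and without
    leakage correction, phase lag index, phase lag time, joint permutation
    entropy) and relative theta power, using permutation tests with
    Benjamini-Hochberg false-discovery-rate control and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
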