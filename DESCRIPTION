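Package: sleepmass
Title: Neural Mass Modelling of Slow-Wave Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a conductance-based cortical neural mass model to
    slow-wave-sleep EEG by multiobjective genetic-algorithm search over a
    bounded 32-parameter space, using two fitness features: the normalized
    Welch power spectrum on a fixed 0.6-10 Hz grid and the mean node degree
    of the weighted horizontal visibility graph. From fitted models it
    extracts hidden emergent properties (population firing rates and
    excitatory, inhibitory, leak and sodium-dependent potassium synaptic
    currents), compares them across subject groups (Mann-Whitney U with
    Bonferroni correction, Jensen-Shannon divergence ranking of parameter
    distributions), simulates in-silico conductance interventions, and
    quantifies each subject's proximity to a spike-wave-discharge (seizure)
    regime. Includes EDF input/output, a synthetic-cohort generator with
    known ground-truth parameters, and a reproducible staged pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
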