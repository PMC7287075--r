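Package: serialTI
Title: Transitive-Inference Task Simulation and Parietal Spike-Train Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of serial-order (transitive inference)
    experiments in which subjects learn the implied ranking of a 7-item list
    from pairwise choices while single-unit activity is recorded. Provides the
    task's combinatorial structure (stimulus pairs, symbolic distance, joint
    rank, counterbalanced block schedules), generative models for choice
    behavior (learning curves, terminal-item effects, spatial win-stay bias,
    saccade latencies) and for spiking units (six temporal-profile families,
    receptive-field gain, joint-rank/symbolic-distance modulation, transient
    rank coding), eye-velocity estimation and saccade detection, spike-train
    epoch rates and kernel-density rate estimates, hierarchical clustering of
    temporal profiles, optimal-linear-estimator population decoding with
    bootstrap confidence intervals, Gaussian-process smoothing of spike counts
    with Welch-test partial eta-squared variance quantification, and
    permutation/bootstrap inference utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
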