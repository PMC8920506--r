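Package: dgexcite
Title: Calcium Imaging and Patch-Clamp Analysis of Dentate Gyrus Excitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging and whole-cell
    electrophysiology of dentate gyrus granule cells in acute brain slice.
    Provides calibration of a slow calcium indicator against ground-truth
    action potentials (linear AP-to-dF/F0 model, normal-fit detection
    threshold at a stated tail probability), dF/F0 computation with
    baseline-window normalisation, activation calls by a mean + 3 SD peak
    rule, spike-count inference by non-negative sparse deconvolution with a
    difference-of-exponentials kernel, hierarchical binomial-probit and
    lognormal mixed-model comparison of activation curves across genotypes,
    paired within-field testing, operating-characteristic simulation, and
    full intrinsic/synaptic feature extraction from current- and
    voltage-clamp sweeps (rheobase, dV/dt spike threshold, half-width, sag,
    firing rates, paired-pulse ratios with baseline extrapolation, E/I
    ratios, one-site binding fits with extra sum-of-squares F tests).
    Includes seeded synthetic-data generators with attached ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest,
    minpack.lm,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
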