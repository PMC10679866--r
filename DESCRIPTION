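Package: thtmito
Title: Mechanistic Modelling and Trace Analysis of Thioflavin T as a
    Mitochondrial Membrane Potential Dye
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-compartment kinetic model of the cationic dyes thioflavin T
    (ThT) and tetramethylrhodamine methyl ester (TMRM) in a mammalian cell:
    Goldman-Hodgkin-Katz potential-driven fluxes across the plasma and inner
    mitochondrial membranes, Hill-type ThT binding/photosensitization, and a
    linear coupling of photosensitized mitochondrial ThT to membrane
    depolarization. Includes scripted in-silico experiments (light-step
    trajectories, dose-by-photosensitization phase grids, sensitivity sweeps,
    FCCP and equilibration emulations), a single-cell fluorescence
    trace-analysis pipeline (baseline and min-max normalization,
    final/initial response ratios, Mann-Whitney U comparison, population
    aggregation, pixel-wise colocalization regression), and a seeded
    synthetic-data generator producing per-cell traces and two-channel
    time-lapse image stacks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
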