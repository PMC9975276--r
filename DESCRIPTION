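Package: ftszdyn
Title: Analysis of FtsZ Protofilament Assembly and Turnover Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of in vitro and in vivo FtsZ
    protofilament dynamics. Estimates GTPase activity and critical
    concentration from regenerative NADH-coupled assay absorbance traces,
    predicts GTP depletion times for single-protein and coassembly
    reactions, extracts assembly amplitudes, initial rates and
    disassembly-onset times from 90-degree light-scattering traces and
    classifies onsets relative to predicted nucleotide depletion, fits a
    two-binding-state reaction-kinetics model to fluorescence recovery
    after photobleaching (FRAP) data, and computes pellet fractions with
    unpaired t-test comparisons for sedimentation assays. Includes a
    seeded synthetic-data generator for every input kind so that each
    estimator has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
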