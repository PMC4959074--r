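Package: lipidpipe
Title: Direct-Infusion FT-ICR Lipidomics Pipeline with a Synthetic Study
    Generator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end untargeted lipidomics workflow for direct-infusion
    and LC Fourier-transform ion cyclotron resonance mass spectrometry peak
    lists: SIM-window stitching, technical-replicate/blank/sample filtering,
    probabilistic quotient normalization, k-nearest-neighbour missing-value
    imputation, QC-calibrated generalized-log transformation, PCA and PLS-DA
    with venetian-blinds cross-validation, permutation testing, VIP-based
    forward selection, per-feature ANOVA with Benjamini-Hochberg FDR control,
    signed percent changes with per-class roll-ups, and exact-mass
    adduct-series lipid annotation.  A deterministic synthetic lipidome
    generator emulates a three-group Wolbachia-infection cell-line study with
    known class-level multiplicative effects, so every stage is testable
    against ground truth without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mixOmics
Config/testthat/edition: 3
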