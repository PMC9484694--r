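Package: rippquant
Title: Intact-Mass and MS/MS Informatics for Modified RiPP Precursor Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying post-translational
    modifications on ribosomally synthesized and post-translationally
    modified peptide (RiPP) precursors from LC-MS and LC-MS/MS data.
    Provides intact-mass prediction for modification states, charge-ladder
    mass deconvolution of electrospray spectra, extracted-compound-
    chromatogram quantification of the fraction of peptide modified via
    skewed-Gaussian peak fitting, b/y fragment-ion annotation of MS/MS
    spectra of (macrocyclic) modified peptides, and a ground-truth
    synthetic-run generator for end-to-end validation. Functions are
    tibble-first and pipe-friendly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
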