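Package: af4saxs
Title: AF4-MALS and SAXS Analysis of Protein Complexes and Binding Stoichiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising protein-protein complexes by asymmetrical
    flow field-flow fractionation (AF4) with multi-angle light scattering (MALS)
    and by small-angle X-ray scattering (SAXS). Implements classical FFF
    retention theory with channel calibration to convert elution times to
    hydrodynamic radii, per-slice Berry (square-root) molar-mass fitting with
    angle-subset co-elution diagnostics, Gaussian deconvolution of fractograms
    with area-based binding-ratio bookkeeping for titrations of a ligand against
    an albumin monomer-dimer mixture, and model-free SAXS primary analysis
    (frame selection and averaging, Guinier fits with automatic range selection,
    regularised pair-distance distribution inversion, Porod invariant and
    volume, molecular-weight estimators, reduced chi-squared comparison, and
    shape factors). A synthetic-data generator produces fractograms and
    scattering curves with known ground truth so that every stage of the
    pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
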