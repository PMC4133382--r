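Package: nitrotyr
Title: Prediction of Protein Tyrosine Nitration Sites from Position-Specific
    Dipeptide Propensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies nitrotyrosine (nitrated tyrosine) sites in protein
    sequences. Tyrosine-centered peptide windows are encoded by the
    occurrence frequencies of ordered residue pairs at each adjacent-pair
    subsite (position-specific dipeptide propensities), estimated separately
    from positive and negative training peptides, and scored by a
    discriminant function with an additive adjust parameter for class
    imbalance. Includes benchmark construction from FASTA plus annotated
    sites, leave-one-out jackknife with decremental count updates,
    stratified k-fold cross-validation, ROC/AUC, a window-size sweep, a
    single-residue baseline encoder, a synthetic benchmark generator with
    controllable planted dipeptide enrichments, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
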