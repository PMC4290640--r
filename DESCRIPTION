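Package: kaapfold
Title: Protein Fold Recognition with k-Separated Amino-Acid Pair Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification for protein fold
    recognition from evolutionary and structural sequence profiles. The core
    method builds k-separated amino-acid pair (k-AAP) features: shifted
    pair-products over the concatenation of a position-specific scoring
    matrix (PSSM) converted to linear probabilities and a predicted
    secondary-structure probability matrix, flattened to 529 features per
    shift and 2116 features for shifts k = 1..4. Includes readers for the
    PSI-BLAST ASCII PSSM and SPINE-X prediction dialects, sequence-based
    baseline feature sets (amino-acid composition, occurrence, ordered pair
    frequencies, profile mono- and bi-grams), RBF-kernel support vector
    machine classification with nested grid search under stratified n-fold
    cross-validation, per-class sensitivity/specificity/precision metrics
    with macro averaging, and a seeded generator of fold-structured
    synthetic profile datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
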