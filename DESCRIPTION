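Package: dimerclass
Title: Classify Activating Receptor Variants from Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to classify activating variants of a homodimeric
    ligand-binding domain into mechanistic classes from conformational
    ensembles. Snapshot ensembles of a two-chain structure are featurized
    into symmetry-averaged pairwise C-alpha or C-beta distances at three
    structural sites (ligand-binding pocket, antagonist-state helix-12
    contacts, and the dimer interface), standardized against the initial
    structure, and classified with a weighted logistic regression trained
    under a sparse group lasso penalty by accelerated proximal gradient
    descent. Includes thresholded feature selection with unregularized
    refitting, accuracy-versus-features curves, per-site feature
    attribution, and a synthetic ensemble generator with planted
    cross-interface distance shifts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
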