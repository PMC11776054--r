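Package: ligandpath
Title: Classify Ligand Unbinding Pathways from Contact-Fraction Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify gas-molecule unbinding trajectories from
    [NiFe] hydrogenase molecular-dynamics simulations into tunnel pathways.
    Trajectories are featurized as per-residue contact fractions (any ligand
    atom within 4 Angstrom of any residue atom) after truncating the
    bound-state segment before bottleneck escape; features are mapped across
    homologous enzymes via BLOSUM62 global alignment with zero-fill and drop
    rules; imbalance-aware binary (adaptive boosting) and multiclass (random
    forest) classifiers are trained with stratified splits and random
    oversampling; models are evaluated with balanced accuracy, multiclass
    Matthews correlation, confusion matrices and ROC/AUC.  A built-in
    synthetic generator produces labeled escape trajectories through a
    radial multi-tunnel toy enzyme so that the whole pipeline is testable
    without external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    ranger,
    rpart,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pROC,
    cluster,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
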