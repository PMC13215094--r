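Package: rclseg
Title: Per-Residue Segmentation of Serpin Reactive Center Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for locating reactive center loops (RCLs) in serine
    protease inhibitor (serpin) sequences by per-residue neural segmentation.
    Provides one-hot and BLOSUM62 residue encoders plus a file-based adapter
    for pre-computed embeddings; three segmentation architectures (a 1D
    convolutional network, an attention-gated 1D U-Net, and a bidirectional
    LSTM) implemented natively with seeded, single-threaded training; masked
    cross-entropy optimisation with early stopping on validation F1;
    residue-level (F1, MCC, accuracy) and per-sequence exact-match
    evaluation; span extraction and export to TSV/GFF3/BED; and a synthetic
    planted-loop sequence generator so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
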