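Package: protpath
Title: Missense Variant Pathogenicity Prediction from Protein Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the pathogenicity (benign versus pathogenic) of
    missense protein mutation sequences by fusing two sequence
    representations: a fixed-dimension embedding from a transformer
    encoder pre-trained with a masked-language-model objective on a
    protein domain corpus, and a Kyte-Doolittle hydropathy encoding of
    the residues.  The concatenated representation is classified by a
    single-hidden-layer perceptron trained with binary cross-entropy.
    Includes FASTA ingestion and amino-acid tokenization, class-imbalance
    augmentation (terminator noise, truncated wild-type negatives),
    ROC/PR evaluation with brute-force-verifiable area computations, and
    a synthetic-data simulator that plants a recoverable hydropathy
    signal so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
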