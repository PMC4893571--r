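Package: rvmlpq
Title: Protein-Protein Interaction Prediction with Relevance Vector
    Machines and Local Phase Quantization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interactions.
    Each protein is represented by a Position Specific Scoring Matrix
    (PSSM), summarized by a 256-bin Local Phase Quantization (LPQ)
    histogram of local Fourier phase signs, reduced by SVD-based
    principal component analysis, and protein pairs are classified by a
    sparse Bayesian Relevance Vector Machine trained by evidence
    maximization. Includes a PSI-BLAST ASCII PSSM reader, an internal
    Dayhoff-matrix PSSM builder, a cross-validation harness reporting
    accuracy, sensitivity, specificity, precision, Matthews correlation
    and ROC curves, a support vector machine baseline, and seeded
    synthetic-data generators for offline benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
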