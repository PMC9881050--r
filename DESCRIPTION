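Package: targetlr
Title: Genome-Wide Prediction of Protein and Peptide Drug Targets with
    Likelihood-Ratio Naive Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes sequence, expression, polymorphism, annotation and
    network features of human proteins (amino-acid class composition, GRAVY,
    theoretical pI, charge, PEST motifs, fold-index disorder, tissue
    specificity, nonsynonymous/synonymous SNP ratio, degree and betweenness
    centrality, transcription-factor in/out-degree), ranks them by minimum
    redundancy maximum relevance (mRMR) with discrete mutual information,
    and fits a likelihood-ratio naive Bayes classifier that scores every
    protein in a genome as a candidate therapeutic target of protein or
    peptide drugs. Includes gold-standard construction with repeated
    negative sampling and sequence-identity redundancy removal, 10-fold
    cross-validation and independent-test evaluation with ROC/AUC,
    target-innovation statistics for approved drugs, and a synthetic genome
    generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
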