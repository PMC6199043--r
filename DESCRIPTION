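Package: tmhkit
Title: Transmembrane Helix Topology, Residue Contact and Accessibility Prediction
Version: 0.1.0
Authors@R: person("tmhkit", "developers", role = c("aut", "cre"),
    email = "tmhkit@example.org")
Description: A desk-scale toolkit for alpha-helical membrane protein sequence
    analysis. Predicts transmembrane helix (TMH) topology from evolutionary
    sequence profiles with a multi-scale evidence-theoretic K-nearest-neighbor
    classifier, median-filter smoothing and a dynamic-threshold segmenter;
    predicts inter-helix residue-residue contact maps by fusing a sparse
    inverse-covariance coevolution engine on multiple sequence alignments with
    a random-under-sampling classifier ensemble; and predicts per-residue
    relative accessible surface area (RASA) by fusing a segment-template
    similarity engine with a kernel regression engine. Ships a seeded
    synthetic-data generator so every engine can be trained and evaluated
    without external structure databases, plus readers and writers for FASTA,
    PSI-BLAST ASCII PSSM and tabular prediction formats, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
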