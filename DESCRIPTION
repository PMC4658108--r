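Package: mirprofiler
Title: Small RNA-Seq miRNA Profiling: Cleaning, Discovery, Differential
    Expression and Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for profiling microRNAs from blood small
    RNA-seq libraries. Implements four-step read cleaning (quality, adapter,
    poly-nucleotide and length filters) with collapsing to unique tags,
    hierarchical non-miRNA annotation under a fixed category priority,
    conserved miRNA quantification against a hairpin catalog, novel miRNA
    discovery from genome-mapped read stacks with a weighted base-pair
    maximization fold, an additive read-signature score and a
    dinucleotide-shuffle structure test, the exact two-library count
    statistic (Audic-Claverie) with reads-per-million normalization,
    zero substitution and low-expression exclusion rules for differential
    expression, and cross-species 3'UTR transfer with seed-anchored miRNA
    target prediction and pathway tallies. Ships a synthetic-data generator
    that plants hairpin precursors, non-miRNA loci and contaminant read
    classes with ground-truth labels for every stage.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
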