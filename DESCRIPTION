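Package: phylodup
Title: Cytonuclear Discordance Detection via Core Phylogenies and Taxon Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes reticulate (hybrid or introgressed)
    taxa from conflicting nuclear (ITS) and plastid sequence partitions.
    Implements a three-phase procedure: (1) per-genome maximum-likelihood
    trees with bootstrap and approximate-Bayes branch supports are scanned
    for strongly supported topological conflicts and the conflicts are
    attributed to individual specimens by leave-one-out testing; (2) a
    "core" phylogeny is built from the congruent specimens only, and each
    incongruent specimen is re-entered as two single-genome entries (taxon
    duplication) whose affinities are located independently on the core
    tree by likelihood placement; (3) the resulting plastid/ITS placement
    patterns are classified against named core clades and "floating ITS
    groups" are detected. Includes a full likelihood engine (time-reversible
    substitution models with discrete-gamma rate heterogeneity, Felsenstein
    pruning, neighbor joining, NNI search, partitioned inference) and a
    synthetic-data generator that plants known hybridization events so
    every stage of the pipeline can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
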