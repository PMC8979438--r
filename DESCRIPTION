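Package: alloscan
Title: Sequence, Network and Elastic-Network Signatures of Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative profiling of single-residue protein variants with
    phenotype labels. Computes per-column Shannon entropy and mutual
    information from multiple sequence alignments, Shrake-Rupley accessible
    surface area and relative accessibility classes, amino-acid contact
    energy networks with mutation-induced centrality changes, Gaussian and
    anisotropic elastic-network dynamics features (mean-square fluctuations,
    perturbation-response effectiveness and sensitivity, mechanical bridging
    score, stiffness), dynamic residue networks with frame-averaged
    betweenness and Floyd-Warshall allosteric path extraction, and group
    statistics (rank tests, Spearman correlations, per-feature ROC/AUC) with
    random-forest phenotype classification under repeated cross-validation.
    A synthetic-data module generates alignments, coarse-grained dimer
    structures, phenotype-labelled mutation sets, contact-count tables and
    mode-sampled trajectory ensembles so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    bio3d,
    Biostrings,
    randomForest,
    yaml,
    readxl
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
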