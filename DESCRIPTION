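Package: sourstore
Title: Storage-Induced Multi-Omics Shifts in Fermentation Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how storage temperature and time restructure
    a fermentation (sourdough-type) microbiome and metabolome. Provides
    compositional transforms (TSS, CLR with multiplicative zero replacement),
    rarefaction and qPCR-based absolute abundance scaling; alpha/beta
    diversity, ordination with correlation biplot vectors, PERMANOVA,
    PERMDISP and a two-level nested PERMANOVA; an abundance-weighted
    co-occurrence network score and cross-validated graphical-lasso
    conditional-dependence networks with per-temperature centrality
    profiling; Procrustes concordance between microbiome and metabolome
    ordinations with permutation tests; enriched/outcompeted log-ratio
    trajectories from differential-abundance tables; metabolite trajectory
    k-means clustering with silhouette/WCSS/gap model selection, phase-binned
    class enrichment and exact-mass annotation; and random-forest
    classification of storage conditions with in-fold feature selection.
    A seeded synthetic-data generator emulating a 3-temperature by 11-day
    by 3-replicate storage experiment with known ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    cluster,
    ranger,
    pROC,
    car,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
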