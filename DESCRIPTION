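Package: epidrift
Title: Neutral-Drift Clone Dynamics, Lineage-Tracing Classification and
    CRISPR Fitness-Screen Statistics for Long-Term Epithelial Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative toolkit for long-term lineage tracing and fitness
    assays in self-maintaining stratified epithelial cultures. Implements the
    analytic single-progenitor neutral-drift model (clone survival, surviving
    clone size, geometric clone-size distribution) with a single-parameter fit
    of the drift rate to cohort summary curves; a stochastic voter-model
    lattice simulation of multicolor (confetti-style) clonal labeling with
    single-colored-area (SCA) extraction; windowed SCA trajectory
    classification (Decay1/2/3, Biphasic, Growing, Steady) and matched-pairs
    signed-rank comparisons; scalar culture statistics (relative fitness,
    stratification ratio, barrier permeability, wound closure rate, expansion
    projections); pooled CRISPR fitness-screen analysis (CPM normalization,
    guide log2 fold change, robust z-scores against nontargeting controls,
    cumulative-fraction depletion AUC, permutation-based FDR gene calls); and
    seeded synthetic-data generators so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
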