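Package: mgwas
Title: Metagenome-Wide Association Analysis for Case-Control Microbiome
    Cohorts
Version: 0.1.0
Authors@R:
    person("mgwas", "developers", email = "mgwas@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for metagenome-wide association studies
    (MGWAS) of shotgun gut-microbiome data: length-normalized gene
    relative-abundance profiling from a non-redundant gene catalogue,
    taxonomic and functional aggregation with identity/coverage
    thresholds, rarefied gene richness and Shannon diversity,
    marker-gene discovery by Mann-Whitney tests on
    stratification-adjusted profiles with Benjamini-Hochberg FDR
    control, co-abundance clustering of markers into metagenomic
    linkage groups (MLGs) with rule-based taxonomy calls, MLG
    co-occurrence networks and phenotype correlations, Bray-Curtis
    PERMANOVA and distance-based redundancy analysis, and random-forest
    case/control classification with importance-ranked feature subsets
    and bootstrap AUC confidence intervals. Includes a synthetic-data
    generator with planted ground truth so every stage is testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
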