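Package: restnet
Title: Graph-Theoretical Analysis of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for whole-brain resting-state functional
    connectivity analysis on binary graphs: head-motion quality control with
    framewise displacement and subject exclusion rules, nuisance regression
    and temporal bandpass filtering of voxel time series, voxel-level degree
    centrality maps, refinement of an anatomical atlas into functionally
    homogeneous sub-regions by spectral community detection, small-world
    metrics against degree-preserving rewired null networks, module and
    participation analysis, and nonparametric group inference with
    permutation tests, FDR control and cluster-extent statistics. Includes a
    seeded synthetic-cohort generator with planted modular structure so the
    full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
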