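Package: hippoclust
Title: Metabolic and Hippocampal Connectivity Phenotyping by Majority-Vote Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratifies resting-state fMRI cohorts into metabolic-connectivity
    phenotypes. Computes within-hippocampus functional cohesiveness and
    hippocampal-segment-to-network integration from voxel-level BOLD time
    series (Fisher Z-transformed Pearson correlations), builds age- and
    sex-adjusted Spearman association matrices over metabolic and connectivity
    measures, and clusters subjects with k-means using a majority vote of 13
    cluster-validity indices to select the number of clusters. Ships a
    synthetic cohort and BOLD factor-model generator that plants a two-cluster
    metabolic-connectivity structure, so the whole pipeline is testable
    end-to-end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    mclust,
    yaml,
    jsonlite,
    RNifti,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
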