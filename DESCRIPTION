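Package: codasc
Title: Compositional Log-Ratio Analysis of Sparse Single-Cell Count Matrices
Version: 0.1.0
Authors@R: person("codasc", "developers", email = "codasc@example.org",
    role = c("aut", "cre"))
Description: Treats single-cell RNA-seq count matrices as compositional data.
    Provides per-cell count-addition schemes that make log-ratio
    transformations (centered, isometric, and housekeeping-gene log-ratios)
    applicable to sparse, high-dimensional matrices; a derivation-backed
    bridge from conventional log-normalized data to the centered log-ratio;
    truncated-SVD dimension reduction approximating exact log-ratio
    analysis; quality-control filtering and highly-variable-gene selection;
    clustering, trajectory, and biomarker evaluation statistics; and a
    gamma-Poisson simulator with logistic dropout and degraded-cell
    spike-ins for benchmarking with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    irlba,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
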