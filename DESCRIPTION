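Package: mitoquant
Title: Mitochondrial Morphometry, Mitophagy Colocalization and
    Expansion-Microscopy Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipelines for fluorescence microscopy of
    mitochondria: per-cell mitochondrial morphometry (count, area,
    membrane-potential-dependent intensity) with automatic
    fragmentation phenotyping, object-based LC3-mitochondria
    colocalization in neurite segments (mitophagy), and 3D
    quantification of protein clusters and their mitochondrial
    association in expansion microscopy with gel-expansion-factor
    voxel calibration. Includes the filtering and thresholding
    operators the pipelines compose (median z-projection, disk median
    filter, white top-hat, 3D Gaussian smoothing, Triangle
    auto-threshold), connected-component labeling with physical
    measurements, a synthetic-scene generator with ground truth for
    validation, and the normalization and group-comparison statistics
    (Welch ANOVA with Dunnett post hoc, Kruskal-Wallis with Dunn post
    hoc, repeated-measures ANOVA with Tukey or Bonferroni post hoc)
    used to compare experimental groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    mvtnorm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
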