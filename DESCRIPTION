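Package: roamdev
Title: Developmental Roaming Behavior and Temporal Individuality Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal analysis of Caenorhabditis elegans locomotion across
    development. Turns frame-level centroid trajectories into roaming/dwelling
    state sequences (rolling speed and angular velocity against a per-stage
    diagonal classifier), segments recordings into larval stages at lethargus
    midpoints, age-normalizes behavior into fixed per-stage time bins, and
    quantifies temporal individuality by fractional ranking, a bias transform,
    weighted-covariance principal component analysis, shuffle-null component
    significance, permutation tests on inter-individual score variance, and a
    consistency index. Includes a synthetic cohort and trajectory generator
    with planted individuality dimensions for validation, stage-level
    population statistics (rank-sum tests with FDR control, size-matched
    comparisons), and worm-size estimation from cropped grayscale frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, BehavioralResearch, TimeCourse, PrincipalComponent
RoxygenNote: 7.3.3
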