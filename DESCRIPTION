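Package: radrep
Title: Reproducibility and Prognostic Value of Radiomic Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end analysis pipeline for studying the joint
    reproducibility and prognostic value of radiomic features extracted from
    3D images reconstructed under varying slice thickness and iterative
    reconstruction strength. Provides synthetic phantom and cohort
    generators, a 93-feature first-order and texture feature extractor with
    2.5D and 3D aggregation across eight resampling settings, pairwise and
    mixed-model generalized concordance correlation analysis, univariate
    survival discrimination by Harrell's C-index, reproducibility-thresholded
    feature selection with minimum-redundancy maximum-relevance inside
    repeated cross-validated Cox proportional hazards modelling, and
    Pareto-efficiency and clustering summaries linking reproducibility to
    prognostic value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    lme4,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
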