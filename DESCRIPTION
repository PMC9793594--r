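Package: idfc
Title: Inter-Individual Deviation of Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how far each subject's resting-state functional
    connectome deviates from a reference cohort using the inter-individual
    deviation of functional connectivity (IDFC) statistic: the mean cosine
    distance between a subject's regional connectivity profiles and those of
    every reference subject. Provides connectome subtyping by k-means
    clustering of network-level deviations with silhouette-based model
    selection, covariate-adjusted two-sample connectivity comparisons at
    region, network and whole-brain scales with false discovery rate and
    Bonferroni control, symptom-severity prediction from network deviations
    by L2-regularized linear support vector regression under leave-one-out
    cross-validation with permutation inference, and a synthetic connectome
    cohort generator with planted subtypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    e1071,
    Matrix,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
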