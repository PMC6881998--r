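Package: touchrsa
Title: Representational Similarity Analysis of Socio-Affective Touch Observation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-voxel representational similarity analysis (RSA) for
    case-control studies of observed social touch. Builds affective
    dissimilarity matrices from valence and arousal ratings, neural
    representational dissimilarity matrices (RDMs) from region-of-interest
    voxel patterns, and fits multiple-regression RSA models with one-sided
    permutation inference and Benjamini-Hochberg false discovery rate
    correction. Includes leave-one-subject-out noise ceilings,
    normality-gated group comparisons with Cohen's d effect sizes, rank
    partial correlations for brain-behaviour analyses, and a synthetic
    cohort generator with known ground-truth structure for end-to-end
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
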