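Package: fimds
Title: F-Informed Multidimensional Scaling for Grouped Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distance-based ordination that reconciles a two-dimensional
    metric multidimensional scaling (MDS) embedding with the result of a
    PERMANOVA test carried out on the original high-dimensional distance
    structure. The embedding is perturbed by a majorization algorithm whose
    objective augments the raw stress with a pseudo-F confirmatory term, so
    that the permutation p-value computed in two dimensions converges to the
    p-value of the original data. Includes the pseudo-F permutation test for
    balanced designs, classical scaling (PCoA) and SMACOF-style metric MDS, a
    supervised-MDS baseline, six embedding quality metrics (trustworthiness,
    continuity, Stress-1, Shepard correlation, F-correlation, F-rank-ratio),
    and a zero-inflated log-normal semisynthetic microbiome data generator
    with group-specific mean-shift schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
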