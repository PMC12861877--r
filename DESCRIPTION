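Package: octx
Title: One-Class Twin Cross-Learning for Texture-Patch Lesion Detection
Version: 0.1.0
Authors@R: person("OCTX", "Maintainers", email = "octx@example.org", role = c("aut", "cre"))
Description: Patch-level detection of lesion-like texture in grayscale
    endoscopy-style images. Implements gray-level co-occurrence (GLCM)
    texture features over non-overlapping patches, a fast double-threshold
    grid search (FDT-GS) that splits score-ranked patches into reliable
    positives, negative samples and uncertain patches, a twin four-class
    fusion decision rule, and a reward-driven positive-only/negative-only
    cross-learning loop with a stochastic retain/remove noise-filter
    policy. Ships a synthetic texture generator emulating imbalanced,
    noise-corrupted lesion channels so the whole pipeline runs without any
    external data, plus confusion-matrix/ROC evaluation and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
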