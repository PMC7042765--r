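Package: nicheshift
Title: Climatic Niche Shift Analysis and Reciprocal Distribution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies climatic niche differences between the native and
    invaded ranges of a species in a gridded environmental space (PCA-env with
    kernel-smoothed, availability-corrected occupancy), computes Schoener's D
    and Warren's I overlap statistics with permutation tests of niche
    equivalency and similarity, decomposes niche change into expansion,
    stability and unfilling, and fits reciprocal presence-background maximum
    entropy distribution models with feature-class and regularization tuning
    (AICc selection, spatial block cross-validation) evaluated by AUC, the
    continuous Boyce index and the true skill statistic. Includes a synthetic
    paired-range landscape generator with a controllable niche shift so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
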