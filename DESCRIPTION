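Package: kdmil
Title: Kernel Density Matrix Inference for Weakly Supervised Histology Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probabilistic classification and ordinal regression with kernel
    density matrices (KDM), unifying fully supervised patch classification
    and weakly supervised, attention-aggregated whole-slide (bag) prediction.
    A KDM represents a probability distribution as a mixture of kernel
    components; inference against a learnable joint KDM over feature-label
    pairs yields a posterior label distribution with an expected value and a
    variance, enabling uncertainty-filtered grading, prototype-based
    interpretation and per-tile uncertainty heatmaps. Includes a synthetic
    histology-like generator (five tissue patterns composing slides whose
    composition determines an ISUP-style grade group), a local-global
    attention pooling module, end-to-end gradient training of prototypes,
    label encodings, kernel bandwidth, attention and an encoder projection,
    and evaluation with quadratic-weighted kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
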