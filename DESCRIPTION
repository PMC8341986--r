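Package: spaced
Title: Spatial Classification of Transcriptomic Subtypes onto Tissue Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns transcriptomic neuron subtypes to anatomical laminae by
    scoring in situ hybridization (ISH) images of subtype-specific marker
    genes. Provides single-cell count-matrix quality control, log
    normalization, Wilcoxon and ROC differential expression, a
    Jensen-Shannon-divergence gene specificity score, marker selection,
    ISH image quantification via IsoData thresholding and ROI area
    fractions with background subtraction, per-layer specificity scores
    with ANOVA and Tukey post hoc layer assignment, cluster-to-cluster
    correlation mapping, a synthetic-data generator with known ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    png,
    tiff,
    optparse
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
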