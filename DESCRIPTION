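Package: nichefab
Title: Inverse Design and Quantification of Mechano-Chemically
    Microstructured Cell Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for flow-lithographic fabrication of
    hydrogel cell niches with spatially microstructured stiffness and
    biochemistry. Provides kernel-weighted interpolation of an empirical
    fabrication state-space, inverse design of printer and photoresist
    variables from desired Young's modulus and linewidth, compilation of
    multi-region niche designs into resist-batched print plans, analysis
    of AFM force-displacement curves (Sneddon conical-indenter fit with
    bottom-effect correction and slip rejection), quantitative image
    analysis of niche-registered cell responses (nuclear:cytoplasmic
    ratios, lipid volume fractions, red-saturation mineralization scores,
    pooled expression maps, four-parameter logistic dose-response fits),
    and synthetic data generators with ground truth for validating every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    lhs,
    mgcv,
    minpack.lm,
    optparse,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
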