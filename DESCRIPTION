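Package: thromboflow
Title: Multiparameter Quantification of Whole-Blood Thrombus Formation Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies platelet thrombus formation on collagen microspots from
    brightfield and three-channel fluorescence microscopy of whole-blood flow
    assays. Computes eight image parameters per microspot (surface-area
    coverage of adhered platelets and multilayered aggregates, discrete
    morphology/multilayer/contraction scores, and positive-area coverage of
    phosphatidylserine, P-selectin and bound fibrinogen), averages them over
    images, duplicate runs and donors, scales them univariately to 0-10, and
    summarises treatment effects as paired-test-filtered subtraction heatmaps
    and cumulative plots. Includes a synthetic microscopy generator with
    per-image ground truth for validating the segmentation and statistics, and
    small utilities for peptide sequence arithmetic (length, substitution
    count, monoisotopic mass).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    yaml,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'stats.R'
    'heatmap.R'
    'peptide.R'
    'segmentation.R'
    'scoring.R'
    'pipeline.R'
    'synthetic.R'
    'render.R'
    'thromboflow-package.R'
    'utils.R'
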