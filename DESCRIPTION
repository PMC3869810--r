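Package: spleenDCE
Title: Semi-Quantitative Spleen DCE-MRI Analysis for Liver Fibrosis Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dynamic contrast-enhanced MRI of the spleen
    with semi-quantitative signal-intensity-time-curve parameters (time to
    peak, positive enhancement integral, maximum slopes of increase and
    decrease). Includes a synthetic phantom and longitudinal-cohort generator
    with analytically known ground truth, a stage-calibrated gamma-variate
    enhancement model, ROI curve extraction with vessel exclusion and
    voxelwise parametric maps, and the staging statistics used for ordinal
    fibrosis grades: Spearman stage correlation, exact and approximate
    Mann-Whitney tests with Bonferroni correction, empirical ROC analysis
    with Youden-index cutoffs, intraclass correlation and Cohen's kappa
    observer-agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    oro.nifti,
    EBImage,
    jsonlite,
    yaml,
    withr,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
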