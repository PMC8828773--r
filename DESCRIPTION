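Package: infarctSeg
Title: Mixed-Supervision Detection and Segmentation of Acute Infarct on
    Paired DWI/ADC MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and segments acute ischemic infarct on paired
    diffusion-weighted (DWI B-1000) and apparent diffusion coefficient
    (ADC) MRI volumes. Implements a z-preserving 3D U-Net whose
    max-pooling acts only within the axial plane, a global max-pooling
    classification head that turns the voxel probability map into a
    study-level call, a mixed-supervision loss combining binary
    cross-entropy over all studies with a soft Dice term restricted to
    studies whose masks are known (segmented positives and negatives),
    balanced batch sampling, 2D-to-3D convolution weight inflation for
    pretraining, percentile intensity normalization, lesion volume
    quantification, and cohort validation statistics (bootstrap AUROC
    confidence intervals, operating-point sensitivity and specificity,
    Dice on true positives, Pearson and Bland-Altman volume agreement,
    Spearman covariate correlations). A built-in stroke-phantom
    simulator generates paired synthetic DWI/ADC cohorts with known
    infarct masks, T2 shine-through confounders and mixed annotation
    regimes so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
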