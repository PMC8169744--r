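Package: cacscore
Title: Automated Vessel-Specific Coronary Artery Calcium Scoring from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end coronary artery calcium (CAC) quantification for gated
    and non-gated chest CT. Implements a two-head slice-wise encoder-decoder
    segmentation model emitting per-pixel calcium and coronary-vessel
    probabilities, a deterministic lesion extraction and Agatston scoring stage
    with vessel attribution (LCA, LAD, LCX, RCA), a gradient-boosted risk-bucket
    classifier for non-gated exams built on slice summary vectors, and the
    agreement and diagnostic statistics used to evaluate automated scoring
    (Bland-Altman, Cohen's kappa, Kolmogorov-Smirnov, sensitivity/specificity at
    clinical cutoffs). A synthetic CT phantom generator with analytically known
    per-vessel Agatston scores makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    xgboost,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
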