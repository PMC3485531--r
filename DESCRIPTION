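Package: stvloss
Title: Segmental Time-Volume Loss Quantification of Left Ventricular
    Mechanical Dyssynchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies left ventricular mechanical dyssynchrony from
    16-segment time-volume curves as produced by three-dimensional
    echocardiography with semi-automated border detection. Implements the
    segmental time-volume loss indices (Pre-STV, Post-STV, total STV),
    which weight each segment's contraction delay by the volume it
    displaces, alongside the traditional timing-only indices (systolic
    dyssynchrony index, latest-minus-earliest delay) and global function
    (EDV, ESV, EF). Includes a cohort evaluation pipeline (responder
    classification by end-systolic volume reduction, ROC analysis with
    Youden cutoffs and DeLong paired AUC comparison, Bland-Altman
    reproducibility, group t-tests, correlation with reverse remodelling)
    and a synthetic generator of segmental curves and paired
    baseline/follow-up cohorts for validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
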