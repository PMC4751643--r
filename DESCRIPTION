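Package: ovcortex
Title: Quantitative Histology of Cryopreserved Ovarian Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing ovarian cortex survival from
    brightfield histology. Quantifies DAB-positive (Ki-67 immunolabelled)
    stromal proliferation in RGB section images via excess-red enhancement,
    maximum-entropy (Kapur) thresholding and morphological cleanup; scores
    primordial follicle morphology and proliferation from annotation tables;
    computes follicle densities per square millimetre on the log10(X+1) scale;
    and compares treatment arms across culture conditions with a linear mixed
    model carrying a random fragment intercept. Includes a synthetic-data
    generator that produces histology images with per-pixel ground truth and
    whole simulated studies with known effect sizes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    lme4,
    lmerTest,
    png,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
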