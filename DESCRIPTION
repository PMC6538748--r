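Package: pcapam50
Title: Iterative PCA-Guided PAM50 Intrinsic Subtyping of Breast Tumors
Version: 0.1.0
Authors@R:
    person("Windber", "Bioinformatics", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Nearest-centroid PAM50 intrinsic subtyping of breast tumor
    expression cohorts with an iterative, expression-derived ER-balanced
    gene-centering subset. Conventional PAM50 centering relies on an
    immunohistochemistry (IHC) based ER-balanced subset; this package
    instead locates an ER boundary on the first principal component of
    the PAM50 panel by minimizing a misclassification statistic, runs an
    intermediate PAM50 pass, and re-centers on the intermediate Basal and
    Luminal A calls to produce refined subtype calls. Includes IHC
    clinical subtyping rules (TN, HER2+, LA, LB1, LB2) with an MKI67
    expression surrogate for Ki67 derived by kernel-density intersection,
    upper-quartile normalization, concordance cross-tabulation, and a
    synthetic cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
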