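Package: lesionmapr
Title: Lesion-Symptom Mapping of Appetite and Weight Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate and mass-univariate lesion-symptom mapping for
    appetite and weight-change outcomes after focal brain lesions. Implements
    partial least squares regression on binary lesion masks with direct total
    lesion volume control (DTLVC), permutation tests of whole-map model fit,
    bootstrap voxel-wise z-statistics and family-wise error control; and
    proportional-subtraction mapping of binarized weight change with
    continuous family-wise error inference at a voxel-extent threshold.
    Includes construction of behavioural outcomes from BDI-II item-18 appetite
    codes and dated weight records, confound regressions, a synthetic
    lesion-cohort generator for validation, and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
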