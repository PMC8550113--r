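Package: fslmm
Title: Fisher Scoring Estimation for Crossed-Factor Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameter estimation and inference for linear mixed models with
    multiple, possibly crossed, random factors using closed-form score vectors
    and Fisher Information matrices. Implements five Fisher Scoring variants
    (joint half- and full-representation updates, simplified coordinate-wise
    updates, and a Cholesky-parameterised update) under maximum likelihood and
    restricted maximum likelihood criteria, with all computation expressed in
    n-independent "product forms" of the design matrices. Supports constrained
    random-effects covariance structures, including the ACE twin model, and
    approximate t-tests with closed-form ("direct") Satterthwaite degrees of
    freedom. Includes a synthetic-data generator and benchmarking harnesses
    for estimation accuracy and degrees-of-freedom calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
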