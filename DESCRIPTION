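Package: het3243
Title: Tissue-Specific Adjustment and Modelling of m.3243A>G Heteroplasmy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for cohort studies of the pathogenic m.3243A>G
    mitochondrial DNA variant. Provides age correction of blood heteroplasmy
    (compound annual decline), sex correction of urine heteroplasmy
    (logit-scale transformation), longitudinal decline estimators,
    small-sample bias-adjusted coefficients of variation for repeated
    measurements, qPCR mtDNA copy-number quantification with standard-curve
    QC and inter-plate standardisation, square-root NMDAS disease-burden
    regressions with bootstrap R-squared model comparison, linear mixed
    models of disease progression with by-subject random slopes and no
    intercept compared by bootstrap AIC, and a synthetic-cohort generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
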