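Package: pcbscan
Title: Sex-Stratified Mixed-Model Transcriptome Scans for PCB Exposure
    and White-Blood-Cell Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcriptome-wide linear mixed-model association scans for
    serum polychlorinated-biphenyl (PCB) exposure in prospective cohort
    data, with a scan-date random intercept, likelihood-ratio tests from
    nested maximum-likelihood fits, Benjamini-Hochberg false-discovery
    control, and PCB-by-leukocyte interaction models. Includes
    reference-based estimation of white-blood-cell fractions from DNA
    methylation (constrained projection), variance-inflation-factor
    screening of covariates, microarray-style preprocessing (pixel-count
    probe filtering, k-nearest-neighbour imputation, quantile
    normalization), power calculation for the general linear model, and a
    synthetic-cohort generator with planted effects so every stage of the
    pipeline can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4,
    limma,
    withr
Config/testthat/edition: 3
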