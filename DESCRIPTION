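Package: iceegnorm
Title: Normative Mapping of Intracranial EEG Band Power Across Age, Sex
    and Hospital
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for building normative maps of
    relative band power (RBP) from multi-centre intracranial EEG.
    Covers interictal segment selection, channel screening, band-pass
    filtering, anti-alias resampling, common average referencing, Welch
    power spectral density estimation and log10/L1-normalised band
    power extraction; contact-to-parcellation assignment under a
    nearest-grey-matter rule; normative data table construction with
    subcortical exclusion and hemispheric mirroring; random-intercept
    linear mixed models with hospital as the grouping factor (REML/ML
    estimation, profile likelihood confidence intervals, likelihood
    ratio tests, AIC/BIC model selection, intraclass correlation and
    marginal R-squared); regional age-coefficient maps; and per-subject
    deviation scoring against the regional normative model. Includes a
    synthetic-data module that generates multi-hospital cohorts from
    the same generative model and raw signals with planted spectra, so
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
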