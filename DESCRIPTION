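Package: kampovig
Title: Pharmacovigilance of Herbal-Medicine-Associated Interstitial Lung Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Signal-detection and risk-modelling toolkit for drug-induced
    interstitial lung disease (DIILD) after exposure to Japanese herbal (Kampo)
    medicines, built around spontaneous-report data in the four-table JADER
    dialect. Provides reporting odds ratios (ROR) with Woolf confidence
    intervals against a whole-database background, reconstruction of daily
    crude-drug intake (Scutellariae radix, Bupleuri radix, Pinelliae tuber)
    from a formulation registry, multivariate logistic modelling with stepwise
    likelihood-ratio selection and adjusted RORs, propensity-score caliper
    matching with standardized-mean-difference balance checks, dose-response
    logistic fits with ROC cutoff analysis, Weibull time-to-onset profiling
    with hazard-type classification, and a synthetic JADER-like data generator
    so the whole pipeline is testable without the public download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fitdistrplus,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
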