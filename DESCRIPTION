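Package: methRhythm
Title: Diurnal Rhythm Analysis of DNA Methylation Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of diurnal (24-hour) rhythmicity in DNA methylation
    array time series and its alteration by total sleep deprivation. Provides
    closed-form cosinor estimation of mesor, amplitude and acrophase,
    five-model differential-rhythmicity classification (arrhythmic, same,
    loss, gain, change) by AIC model selection with an Akaike-weight
    confidence cutoff, white-blood-cell count normalization with
    adjacent-timepoint imputation and a composition-correlation null check,
    paired matched-clock-time differential methylation with an empirical
    Bayes moderated t-test, threshold-grid bookkeeping of differentially
    methylated positions, gene-set over-representation on user-supplied
    sets, and a synthetic-data generator emulating a 15-subject, 16-sample,
    3-hour-resolution sleep-deprivation study design with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
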