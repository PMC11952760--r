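Package: benfordeco
Title: Benford's Law First-Digit Conformity Testing for Ecological Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether sets of positive ecological measurements
    (biomass, abundances, cell counts) conform to the Newcomb-Benford
    first-significant-digit distribution, and to interpret departures as
    signals of impending ecological state transition.  Implements
    first-digit extraction and tallying, the Morrow sample-size-scaled
    Euclidean distance, the Kossovsky sum of squared deviations, the
    Cohen-W effect size, per-digit Pearson residuals, Kullback-Leibler
    relative entropy in Hartley units, a digit-probability Simpson
    diversity index, threshold-based state classification with a
    weight-of-evidence verdict, bootstrap confidence intervals, Kendall
    rank agreement between tests, log-log power-law fits (including
    Taylor's mean-variance power law on digit-partitioned data), packaged
    ecological case datasets, and synthetic-data generators for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
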