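Package: shrubrings
Title: Cross-Dating and Growth-Variability Analysis for Multi-Stemmed Shrubs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dendrochronological analysis of multi-stemmed shrubs
    measured along several radii per shoot and several shoots per clonal
    individual (stock). Provides readers and writers for Tucson decadal
    (.rwl) and delimited ring-width tables with hierarchical metadata,
    conservative detrending (negative exponential or negative-slope linear)
    to dimensionless indices, cross-dating synchrony statistics
    (Gleichlaeufigkeit with significance, overlap-adjusted correlation and
    the Baillie-Pilcher t score), chronology homogeneity statistics (mean
    sensitivity, first-order autocorrelation, Rbar, signal-to-noise ratio,
    expressed population signal, first-eigenvector variance), an
    EPS-driven sample-size calculator, a three-level (radius within shoot,
    shoot within stock, stock versus stock) comparison pipeline with
    extreme-year tests and FFT low-pass growth trends, and a seeded
    generator of synthetic shrub ring-width stands for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
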