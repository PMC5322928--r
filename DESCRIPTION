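Package: arrivalwatch
Title: Detecting Species Arrivals from Social-Media Text Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Syndromic-style surveillance of species arrival events in a
    social-media text stream. Provides boolean keyword queries (taxonomic,
    common-name and symptomatic, the latter mined from a seed corpus by
    frequency analysis after stopword removal and Snowball stemming),
    signal-to-noise estimation with month-stratified subsampling of labelled
    hits, weekly-count aggregation, autoregressive prewhitening and CUSUM
    control charts of the standardised residuals, seasonal (Spring-window)
    detection rules validated against ground-truth survey series, and a
    synthetic tweet-stream generator with the statistical structure the
    analysis assumes, so the whole pipeline runs without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
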