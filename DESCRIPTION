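Package: rpcross
Title: Recurrence Plot Analysis with Automatic Cross Detection for
    Interaction-Count Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recurrence plot analysis for univariate, equally spaced time
    series of molecular interaction counts (hydrogen bonds, hydrophobic-polar
    contacts) from molecular dynamics simulations. Provides automatic
    delay-embedding parameter selection (delay by first non-significant
    autocorrelation, dimension by the Cao method, majority voting across
    series), recurrence matrix construction with recurrence-rate targeted
    thresholds, Shannon entropy of diagonal recurrent line lengths scanned
    over the recurrence rate with automatic selection of the working rate at
    the edge of log-log linearity, and automatic detection of dark and white
    cross patterns marking windows of anomalous dynamics. Includes a seeded
    synthetic-data generator emulating the statistical structure of
    aggregation count series so the whole pipeline is testable without
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
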