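Package: scrscore
Title: Semi-Automated Trough-to-Peak Scoring of Event-Related Skin
    Conductance Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores event-related skin conductance responses (SCRs) by
    threshold-validated trough-to-peak detection in the first, second, and
    third interval latency windows (FIR, SIR, TIR) used in fear-conditioning
    research.  Provides high-pass filtering and bin-mean resampling of the
    raw conductance trace, per-trial segmentation around event markers,
    a programmatic override workflow in place of interactive adjustment,
    CSV annotation output, and rater-agreement statistics (one-way
    random-effects agreement intraclass correlation, Bland-Altman limits of
    agreement, Pareto tabulation of discrepancy causes).  A built-in
    simulator generates differential fear-conditioning sessions with known
    ground truth so the full pipeline can be exercised without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
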