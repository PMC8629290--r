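Package: synoptic
Title: Synoptic Water-Chemistry Survey Analysis: Persistence, Patch Size,
    and Subcatchment Leverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing infrequent but spatially extensive
    ("synoptic") water-chemistry surveys of streams and lakes, such as
    national monitoring programmes. Implements paired change testing of
    repeat sites between survey campaigns, spatial persistence of
    concentration rank patterns via Spearman correlation, patch-size
    estimation through variance-collapse changepoint detection (a
    from-scratch PELT implementation with false-positive screening), and
    subcatchment leverage with critical-source-area accounting. Includes a
    synthetic survey generator with controllable rank persistence, patch
    structure, critical sources, nondetects and between-survey trends, so
    every stage of the pipeline can be exercised and validated without
    access to the original monitoring data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
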