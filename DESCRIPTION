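Package: actisleep
Title: Actigraphy Sleep-Period Detection, Parameter Optimization and
    Method Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving sleep from wrist-worn accelerometer
    activity counts recorded in one-minute epochs: Cole-Kripke sleep/wake
    scoring, Tudor-Locke sleep-period detection with its five tuning
    parameters, the ten standard actigraphy sleep measures with daily
    aggregation, a per-minute percentage-of-agreement (Jaccard) statistic
    against self-report sleep logs, an exhaustive grid-search sensitivity
    analysis over the Tudor-Locke parameters, and a method-comparison
    layer (repeated-measures Bland-Altman limits of agreement, exact
    Wilcoxon signed-rank tests, missed-night accounting). A seeded
    synthetic actigraphy cohort generator with known ground truth allows
    the full pipeline to run and be tested without access to raw study
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
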