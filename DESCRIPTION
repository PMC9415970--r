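Package: breathalert
Title: Personal Baseline Alerts from Respiration-Belt Breathing Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects irregular breathing episodes in single-channel
    respiration-belt recordings by learning a personal baseline
    distribution and flagging outlier windows. Extracts sliding-window
    features (moving maximum, moving minimum, amplitude, FFT dominant
    frequency), fits per-person baselines three ways (Gaussian mean plus
    or minus alpha standard deviations, empirical quantile thresholds,
    and a jittered bivariate rectangular outlier frame over two
    channels), and emits per-window alerts with summary statistics.
    Includes a protocol-driven synthetic breathing-signal simulator so
    the full pipeline runs without any recorded data, and a command-line
    interface covering simulate, train, detect and report stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    zoo
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
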