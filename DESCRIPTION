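Package: eegcsa
Title: Mental-Task EEG Classification with Yule-Walker Features and a
    Crow-Search-Optimised Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trial classification of four imagined command words
    (forward, right, left, stop) from two-channel EEG. Trials are cleaned
    with a 50 Hz notch filter, summarised by an order-21 autoregressive
    model fitted through the Yule-Walker equations (Levinson-Durbin
    recursion) and its parametric power spectral density, and classified
    by a single-hidden-layer feed-forward network whose weights are
    optimised by the crow search algorithm instead of backpropagation.
    Includes a synthetic EEG generator reproducing the acquisition
    protocol (20 subjects, 4 tasks, 10 trials per task, 5 s at 200 Hz),
    single-trial recognition accounting, per-subject accuracy statistics,
    and a reproducible end-to-end pipeline with a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
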