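Package: cadtqueue
Title: Queueing-Theoretic Evaluation of AI Triage Wait-Time Savings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mean wait-time savings that a computer-aided
    triage and notification (CADt) device delivers to diseased patient
    images when it re-prioritizes a radiology reading queue. Implements
    preemptive-resume priority queueing models solved by the
    matrix-geometric method with recursive dimensionality reduction,
    Erlang-Coxian phase-type matching of busy-period moments, a paired
    two-world discrete-event simulator for verification and confidence
    intervals, and ROC-indexed time-savings maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    Matrix,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
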