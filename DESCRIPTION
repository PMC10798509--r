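Package: pwlsgait
Title: Performance-Weighted Regression for Reflex-Based Walking Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building velocity-indexed parameter modulators for
    reflex-based bipedal walking controllers. Implements Hill-type muscle
    actuator dynamics, stance/swing reflex stimulation laws with sensory
    delays, the gait objective combining velocity tracking, posture and
    metabolic cost of transport (CoT), CMA-ES dataset collection over an
    incremental target-velocity schedule, and performance-weighted least
    squares (PWLS) polynomial regression in which each gait record is
    weighted by its CoT relative to the local mean. Includes a deterministic
    surrogate gait evaluator so the full collect-fit-analyse pipeline runs
    at desk scale, plus integrated-CoT efficiency analysis and
    reflex-circuit substitution experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
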