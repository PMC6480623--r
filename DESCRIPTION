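Package: gaitstride
Title: Automated Running Gait Event Detection from Wearable Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects initial contact (IC) and toe off (TO) events in
    steady-state running from foot- and low-back-mounted tri-axial
    accelerometers, and from vertical ground reaction force as the
    force-plate gold standard. Implements a real-time-emulating sliding
    window engine with cadence-constrained candidate consolidation,
    left/right step-side assignment from the low-back mediolateral axis,
    event matching with skipped-step accounting, Bland-Altman agreement
    statistics, per-condition back-foot summaries, a parameter-grid
    runner, and a synthetic gait signal simulator with exact ground-truth
    event labels for validation.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
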