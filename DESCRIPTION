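Package: pumpguard
Title: Near-Miss Analytics for Smart Infusion Pump Event Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mines dose-error-reduction-software (DERS) event logs from smart
    infusion pumps for near-miss "good save" corrections: groups time-stamped
    pump events into alert sequences, pairs cancelled programs with their
    replacement programs, classifies cancellation causes (wrong medication,
    wrong dose, wrong channel, concentration-limit breach, calculator exit,
    indeterminate), and summarizes clinician decision times, dose-error
    factors, alert mix, and medication-library compliance. Includes
    lookalike-soundalike (LASA) drug-name analytics (TALLman-aware name
    normalization, divergence-position classification, character-count
    distributions, formulary confusability screening) and a seeded synthetic
    event-log generator with a ground-truth file so every stage is testable
    without hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
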