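Package: eetsim
Title: Microsimulation of Extended Endocrine Therapy Duration in ER-Positive Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time, event-driven microsimulation comparing 5 versus 10
    years of adjuvant endocrine therapy (tamoxifen, tamoxifen with ovarian
    suppression, or an aromatase inhibitor) for women diagnosed with
    estrogen-receptor-positive, non-metastatic breast cancer. Simulates paired
    life histories per woman under common random numbers, with calibrated
    baseline breast-cancer mortality, Gompertz-Makeham competing mortality,
    strategy-level hazard-ratio treatment effects, adverse-event sampling with
    dated utility decrements, discounted life-year and QALY integration, and
    one-way/two-way/completion-rate sensitivity analyses with tornado output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
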