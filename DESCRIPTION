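Package: biledrain
Title: Cost-Minimization Analysis of Biliary Drainage Strategies After Failed ERCP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost comparison of endoscopic ultrasound-guided
    biliary drainage (EUS-BD) and percutaneous transhepatic biliary drainage
    (PTBD) as salvage strategies after failed ERCP in malignant distal biliary
    obstruction. Implements a 30-day cost-minimization decision model from a US
    Medicare payer perspective with probabilistic sensitivity analysis
    (beta-distributed re-intervention probabilities, Monte Carlo) and one- and
    two-way deterministic sensitivity analysis with closed-form cost-equivalence
    thresholds; a per-patient trial-level cost comparison (median and range
    summaries, Mann-Whitney tests, bias-corrected bootstrap confidence
    intervals for between-arm cost differences); and a seeded synthetic
    two-arm trial generator so the trial-level pipeline is fully testable.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
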