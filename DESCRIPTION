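Package: missr
Title: Midwifery Integration Scoring and State-Level Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Midwifery Integration Scoring System (MISS), a
    weighted 50-item composite instrument that scores each US jurisdiction's
    regulatory environment for midwifery practice, together with the
    ecological analysis pipeline built around it: workforce density and
    birth-setting access metrics, normality-gated Spearman rank correlations
    between integration scores and perinatal outcomes, hierarchical
    block-entry regressions testing the variance in outcomes explained by
    integration beyond the proportion of non-Hispanic Black births, quartile
    report cards, and a fully deterministic synthetic jurisdiction generator
    so every stage of the pipeline can be exercised without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    datasets,
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
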