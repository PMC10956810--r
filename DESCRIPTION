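Package: hccmarkov
Title: Markov Cohort Cost-Utility and Budget-Impact Model for
    Unresectable Hepatocellular Carcinoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Three-state Markov cohort model (progression-free,
    progression, death) evaluating atezolizumab plus bevacizumab against
    best supportive care for unresectable hepatocellular carcinoma from a
    societal perspective.  Provides hazard-ratio-based transition
    probability construction, background-mortality adjustment from an
    age-specific life table, annual-step discounting, deterministic and
    probabilistic cost-effectiveness analysis (ICER, net monetary
    benefit, cost-effectiveness acceptability curves), one-way
    sensitivity analysis (tornado), and a five-year budget-impact
    projection with an access-rate ramp.  All results are returned as
    tibbles with broom-style tidy() and glance() methods and ggplot2
    autoplot() methods.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
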