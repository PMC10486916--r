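Package: beanrisk
Title: Probabilistic Health Risk Assessment of Toxic Elements in Beans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic dietary health-risk assessment of
    potentially toxic elements (As, Cd, Cr, Hg, Pb) in beans and similar
    staple foods: preparation of left-censored (non-detect) concentration
    records with the WHO LOD/2 substitution rule, descriptive summaries and
    maximum-limit screening, Spearman correlation with strength categories,
    Kruskal-Wallis screening and Ward clustering of sampling areas, and
    Monte Carlo estimation of estimated daily intake (EDI), target hazard
    quotients (THQ), hazard index (HI) and carcinogenic risk (CR) with
    percentile, exceedance and contribution-to-variance sensitivity
    summaries. Includes a seeded generator of synthetic censored,
    correlated lognormal concentration data for testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
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
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
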