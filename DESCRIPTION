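Package: ecotoneburn
Title: Fire Severity and Carbon Combustion Accounting at the Forest-Tundra Ecotone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing wildfire burn depth from biometric proxies
    (adventitious root and tussock crown heights), soil-monolith carbon arithmetic
    and hierarchical depth-carbon modelling, combustion-class aboveground carbon
    loss, plot-level carbon budgets, understory community-change statistics
    (Bray-Curtis distance, presence-absence turnover, strata-respecting PerMANOVA),
    and post-fire regeneration accounting, together with a synthetic-study
    generator that emulates the sampling design of a boreal forest-tundra ecotone
    wildfire study so every stage can be exercised end to end without field data.
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
    nlme,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
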