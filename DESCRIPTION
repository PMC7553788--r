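Package: infodemics
Title: Collective Online Attention to Epidemics: Memory-Kernel Regression and Dynamic Topic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for infodemiology: quantify how media coverage and epidemic
    incidence drive collective online attention. Implements exponential-memory
    covariate regression models of attention volume with time-scale tuning and
    non-nested (Cox) and nested (F) model comparison, country-attributed
    normalization of per-article page-view signals, corpus relevance and
    quality filters for news and discussion-platform data, TF-IDF + projected
    gradient nonnegative matrix factorization topic modeling with fixed-basis
    projection, topic strength/relevance/half-relevance-time dynamics and
    interest-share comparison, regular-expression self-report geolocation with
    a bundled gazetteer, and a fully seeded synthetic-data generator emulating
    every input so the complete pipeline is testable offline.
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
    rlang,
    stats,
    tibble,
    utils
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
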