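Package: incprev
Title: Incidence Trends and Aging-Out Prevalence Models for Annual Disease Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating disease prevalence from national-registry
    annual incidence counts when only a short observation window exists.
    Fits linear and log-linear (exponential) trends to the early rise of an
    annual incidence rate, reconstructs pre-observation incidence under
    alternative historical start points, and accumulates prevalence with a
    recursive cohort model in which diagnosed cases exit only by aging out
    of the population. Includes confidence-interval propagation from the
    plateau-era incidence, forward projection under constant incidence and
    geometric population growth, a synthetic-registry generator with Poisson
    case counts for validation, and ggplot2 graphics. Ships the Slovenian
    ADHD registry table (1997-2013) as a worked fixture.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
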