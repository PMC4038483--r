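Package: pondshift
Title: Distribution-Abundance Relationships and Regime Shifts in Pond
    Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for long-term amphibian pond-metacommunity
    surveys: habitat availability and constrained occupancy estimation,
    distribution-abundance (d-a) curve fitting with small-sample AIC model
    selection and segmented (breakpoint) regression, sequential t-test
    regime-shift detection (STARS) with regime shift indices, incidence-function
    (Hanski) and circuit-theory connectivity, phylogenetically independent
    contrasts, lagged cross-correlation diagnostics, and a synthetic
    metacommunity generator with drought forcing and known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
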