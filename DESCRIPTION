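Package: occudyn
Title: Non-Equilibrium Drug-Target Occupancy Under Binding-Site Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models dynamic drug-target occupancy when the binding site itself
    builds and decays, either through synthesis and degradation of the
    site-bearing species or through gating of a binding-competent
    conformational state. Provides closed-form and numerical solutions of the
    non-equilibrium binding rate equation, dimensionless recasting (alpha,
    beta, gamma groups), koff hijacking by site decay, steady-state /
    quasi-steady-state / non-steady-state occupancy profile classification,
    the konSS kinetic-tuning rule, Hill and competitive occupancy algebra,
    and case studies for PCSK9-LDL receptor binding, hERG channel blockade,
    and the binding-kinetic profiles of marketed drugs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
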