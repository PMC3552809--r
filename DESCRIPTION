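Package: msbackcalc
Title: Multi-State Back-Calculation of Hidden-Onset Incidence from
    First-Registration Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates yearly incidence of a hidden onset process (the
    motivating application is heroin use in Spain) from individual records of
    onset year and year of first registration (first treatment ever), under
    assumed yearly exit rates for mortality and permanent cessation.  A
    three-state model with Poisson immigration yields a simple deconvolution
    likelihood which is maximised over yearly incidence and yearly
    registration probabilities, with registration probabilities before the
    observation window fixed by a flat-plus-linear-ramp rule linked to the
    first estimated year.  Includes leaving-rate schedule builders,
    sensitivity scenarios over cessation and mortality assumptions, a
    two-part bootstrap (case resampling plus gamma perturbation of assumed
    rates), goodness-of-fit diagnostics, a stochastic career simulator for
    validation, and rate conversion against population denominators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
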