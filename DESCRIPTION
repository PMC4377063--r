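Package: episodizer
Title: Infectious Episode Construction and Incidence Modelling for
    Prospective Childhood Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduces prospective parental illness reports (ICD-10 codes and
    standalone fever answers) into time-bound infectious episodes of four
    classes (respiratory, gastrointestinal, other, unknown febrile) using
    category-constrained gap chaining, and computes person-time incidence
    rates and covariate rate ratios from log-link Poisson models with a
    person-years offset.  Ships an editable ICD-10 category catalog, a
    seeded synthetic cohort generator with ground-truth episode labels, an
    exhaustive reference implementation of the merging rules for
    verification, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
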