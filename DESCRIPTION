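Package: nkabm
Title: Agent-Based Simulation of Tumor and NK-Cell Dynamics in Adoptive
    Cell Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An on-lattice stochastic agent-based simulator of the tumor
    microenvironment under natural-killer (NK) cell adoptive therapy.
    Tumor cells and three NK phenotypes (cytotoxic, exhausted, vigilant)
    interact on a 2D Moore-neighborhood grid with a decaying cytokine
    field. Cytotoxic killing follows a logistic probability modulated by
    per-agent genetic effects, CAR engineering, and tumor immune evasion;
    NK proliferation follows a cytokine- and tumor-load-dependent Hill
    model; serial-killing capacity depletion drives exhaustion. Includes
    dosing-schedule in-silico trials, MSE-driven grid-search calibration
    against observed tumor-progression curves, random-forest sensitivity
    analysis, and synthetic-data fixtures so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
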