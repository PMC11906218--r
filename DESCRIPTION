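Package: dmfsort
Title: Simulation and Droplet Routing for Label-Free Cell Sorting on
    Digital Microfluidic Chips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the statistics and logistics of image-activated,
    label-free cell sorting on an active-matrix digital microfluidics
    (AM-DMF) electrode array. Provides the Poisson droplet-loading model
    (concentration to occupancy-mean conversion, droplet typing,
    closed-form type proportions, chi-square goodness of fit), a
    stochastic virtual classifier with per-object misclassification, an
    iterative sort-collect-replenish cycle engine with recovery and
    purity accounting, a modified Safe Interval Path Planning (SIPP)
    algorithm for collision-free multi-droplet routing with a
    one-electrode safe distance, and scripted simulation studies
    (precision sweeps, ratio sweeps, cycle studies, and a rare-cell
    pre-sorting strategy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
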