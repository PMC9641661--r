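Package: mir9step
Title: Stepwise miR-9 Inputs and Escape from Perfect Adaptation in a
    Her6 Gene Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dynamical models of the zebrafish Her6/miR-9 regulatory
    network during hindbrain neurogenesis. Implements an incoherent
    feed-forward loop in which Her6 adapts perfectly to the mature
    miR-9 input, and an extended circuit in which a self-activating,
    mutually repressive downstream target turns the network into a
    bistable switch that responds to sharp stepwise increases of
    miR-9 but not to gradual ones. Includes constructors for
    deterministic and fluctuating miR-9 input profiles, a single-cell
    generator of stepwise population inputs from sequential, additive
    activation of paralogous miR-9 loci, fixed-point and stability
    analysis, outcome classification, switching-threshold search, and
    scripted, seeded experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
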