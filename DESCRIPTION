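Package: pcbfate
Title: Stream PCB Fate, Food-Web Bioaccumulation, and Remedy Decision Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linked desk-scale models for polychlorinated biphenyl (PCB)
    dynamics in a small karst-fed stream network: quasi-steady one-dimensional
    Manning hydraulics and conservative tracer transport, flow-rated boundary
    sources with first-order temporal decay, a coupled water-column/sediment-bed
    chemical mass balance (partitioning, settling, resuspension, volatilization,
    porewater exchange, bioturbation, burial), a bioenergetics-based food-web
    bioaccumulation model for stream fish, a remedial-alternative scenario engine
    with bounding-calibration uncertainty analysis and post-remedy delay
    adjustment, compliance (remedy-confirmation) statistics with
    success/failure/inconclusive outcomes, and a synthetic monitoring-data
    generator so the whole pipeline is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
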