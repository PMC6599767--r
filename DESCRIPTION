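Package: gcxmech
Title: Glycocalyx Mechanotransmission of Pulsatile Wall Shear Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiscale analysis of how the endothelial glycocalyx transmits
    pulsatile haemodynamic wall shear stress (WSS) to its transmembrane
    anchors. Provides a seeded generator of phenotype-controlled pulsatile
    WSS vector fields on triangulated surface patches, a dynamic Timoshenko
    beam finite-element model of the heparan-sulfate/glycocalyx unit with
    Newmark time integration and anchor-reaction extraction, time-domain
    descriptors (TAWSS, OSI, time-averaged force, force ratio, oscillatory
    force index), frequency-domain descriptors (spectral power ratio,
    dominant-harmonic ratio), percentile-region co-localization via the
    similarity index, and a reproducible end-to-end pipeline with VTK/CSV/
    JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
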