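Package: perchsense
Title: Sensor Placement and Foot-State Estimation for Perching Balance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study where a balance sensor should sit on a perched,
    serially compliant biped. Simulates a lumped-parameter body (platform-attached
    feet, spring-loaded legs, hip mass, neck of selectable stiffness, head mass)
    excited by random center-out-and-back platform displacements, and analyses the
    resulting foot, hip and head accelerometer traces: effective stiffness from the
    spectral resonance of head acceleration, mechanical propagation delays from
    cross-correlation maxima, and reconstruction of foot acceleration from hip or
    head sensing by MOESP subspace identification of a discrete-time state-space
    model, scored with the variance-accounted-for (VAF) statistic. Window-bootstrap
    resampling and two-sample comparisons quantify uncertainty, and an experiment
    driver runs the full trial grid end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    Matrix,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
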