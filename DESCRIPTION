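Package: infoflow
Title: Information Transfer Mapping over Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates the transfer of task information between brain regions
    and networks by mapping task-evoked activation patterns through
    resting-state functional-connectivity weights (activity flow mapping) and
    decoding the mapped patterns with a cross-validated match-versus-mismatch
    representational similarity analysis. Includes multiple-regression and
    principal-components-regression connectivity estimation, between-network
    global connectivity, miniblock task GLMs, max-statistic permutation
    family-wise error correction, behavioral decoding from information
    estimates, and a firing-rate network simulator with a hemodynamic forward
    model that provides a ground-truth validation bed with a known hub
    community.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
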