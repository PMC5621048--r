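Package: hmidecode
Title: Decoding Hand Motor Imagery from EEG with Choi-Williams
    Time-Frequency Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding eleven hand motor-imagery tasks from
    multichannel EEG. Implements a quadratic time-frequency engine
    (Wigner-Ville and Choi-Williams distributions via the ambiguity
    domain), twelve time-frequency features in five categories, a
    four-layer hierarchical classifier built from RBF support vector
    machines with one-against-one multiclass nodes, subject-dependent
    (10-fold) and subject-independent (leave-one-subject-out)
    evaluation harnesses, and a synthetic motor-imagery EEG generator
    for end-to-end testing without access to recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
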