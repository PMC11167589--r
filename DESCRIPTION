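Package: mpfcharge
Title: Coordinate-Free Message-Passing Featurization for Atomic Partial
    Charge Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coordinate-free molecular graphs from SMILES or TRIPOS
    mol2 input, featurizes every atom with a parameter-free message-passing
    featurizer (bond, atom and self contribution terms after a fixed number
    of neighbourhood update rounds, plus mean neighbouring electronegativity
    and self-electronegativity), and trains a small dense tanh network to
    regress per-atom partial charges from the five-feature descriptor.
    Featurization scales quadratically and prediction linearly with atom
    count, so molecules of any size can be predicted without retraining.
    Includes a synthetic molecule and label generator for end-to-end testing,
    model persistence, the standard accuracy indicator set, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
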