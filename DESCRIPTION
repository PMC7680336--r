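Package: phylosym
Title: Phylosymmetric Rate-Matrix Algebras from Rooted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construct parameterised substitution models from rooted trees by
    assigning a rate to every non-leaf vertex and defining the rate of change
    between two states (leaves) as the rate at their most recent common
    ancestor.  Builds the resulting basis of symmetric zero-row-sum rate
    matrices, the associated tree-induced graph sets whose negative Laplacians
    realise the basis, the closed-form multiplication structure of the span,
    and an exact decision procedure for whether a pattern of rate equalities
    still yields a matrix algebra.  Includes a seeded random-tree generator,
    in-package fixtures (including the Kimura two-parameter model), symbolic
    model export, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
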