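Package: mhcvote
Title: Mixed-Descriptor Voting-Ensemble Classification of MHC Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein sequences with five classical descriptor
    families (188-dimensional composition/transition/distribution features,
    amphiphilic and type-1 pseudo amino acid composition, k-spaced conjoint
    triads, and k-spaced amino acid group pairs), classifies major
    histocompatibility complex (MHC) versus non-MHC proteins with a
    hard-voting ensemble of a random forest, an SMO-trained support vector
    machine and an SGD-trained linear classifier, and evaluates models with
    sensitivity, specificity, accuracy and the Matthews correlation
    coefficient under stratified cross-validation or an independent hold-out
    split. Includes a seeded synthetic two-class sequence generator so the
    whole pipeline is testable without external data, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
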