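Package: symtriage
Title: Symptom-Only Disease Prediagnosis with a Hierarchical Classifier Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for symptom-only medical prediagnosis and triage. Diseases are
    organised in a three-level hierarchy (main category, subclass type, specific
    disease) with an arithmetic integer code scheme, and binary symptom records are
    classified level by level with either a from-scratch single-hidden-layer
    backpropagation network (sigmoid hidden units, softmax output, cross-entropy
    loss, optional per-sample weights) or a from-scratch one-vs-rest soft-margin
    linear support vector machine fitted by dual coordinate descent. Includes
    leave-one-out cross-validation harnesses, concurrent-disease (composite class)
    classification, and a seeded synthetic symptom-record generator with
    per-disease characteristic symptom profiles, sibling overlap and flip noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
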