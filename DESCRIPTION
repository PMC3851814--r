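Package: ppilink
Title: Protein-Protein Interaction Prediction from Heterogeneous
    Similarity Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores protein pairs with three Gene Ontology semantic
    similarities (TCSS, IntelliGO, Wang), a co-pathway Jaccard similarity
    and three network-topology link-prediction similarities (Jaccard,
    Adamic-Adar, resource allocation), then trains a support vector
    machine on gold-standard positive and degree-preserving sampled
    negative interactions to flag false-positive and recover
    false-negative interactions.  Includes OBO/GAF/edge-list readers,
    stratified cross-validation with ROC/AUC evaluation, and seeded
    generators of synthetic binary-style and co-complex-style benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
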