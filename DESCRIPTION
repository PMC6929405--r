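Package: grsmf
Title: Synthetic Lethality Prediction via Graph-Regularized
    Self-Representative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts synthetic-lethal (SL) gene interactions from a known
    SL pair list and a gene functional-similarity matrix. The model
    represents the symmetric SL adjacency matrix X by itself, X ~ U'XU,
    with each column of the coefficient matrix U constrained to the
    probability simplex, an l2 penalty on U, and a graph-Laplacian penalty
    that pulls functionally similar genes toward similar representation
    rows. The objective is minimized with relaxed majorization-minimization
    multiplicative updates. Includes 5-fold cross-validation with AUC,
    hyperparameter grid search and sensitivity sweeps, a seeded generator
    of planted-structure SL networks with a correlated similarity matrix,
    candidate ranking of unknown pairs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
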