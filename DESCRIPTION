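Package: lncwalk
Title: Bi-Random Walks on Laplacian-Normalised Heterogeneous Networks for
    lncRNA-Disease Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Prioritises candidate lncRNA-disease associations by network
    propagation. From a binary association matrix it builds Gaussian
    interaction-profile kernel similarities for lncRNAs and diseases, fuses
    the lncRNA kernel with Spearman expression similarity, applies a logistic
    transform to the disease kernel, Laplacian-normalises both similarity
    networks, and runs bi-random walks with restart on the coupled
    heterogeneous network. Includes a leave-one-out cross-validation harness
    with ROC/AUC summaries, per-disease candidate ranking, and a seeded
    generator of synthetic block-structured networks with partial expression
    profiles for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
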