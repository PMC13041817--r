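Package: netreconcile
Title: Attribute-Aware Reconciliation of Signed Directed Interaction
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies newly extracted molecular interactions against a
    curated baseline knowledge graph. Each new interaction in a tabular
    interaction list is compared with the baseline network's directed,
    signed, attributed edges and multi-edge paths, and assigned to one of
    four categories (corroboration, contradiction, flagged, extension)
    with finer subcategories. Mismatch semantics are configurable through
    three classification schemes and nested attribute-inclusion
    strategies, so the strictness of reconciliation can be tuned to the
    modelling objective. Includes readers and writers for the tabular
    interaction dialect used by curated mechanistic models, a synthetic
    fixture generator with planted ground-truth labels, an independent
    brute-force reference classifier, summary statistics for category
    distributions and baseline coverage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
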