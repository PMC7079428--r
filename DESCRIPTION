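Package: duonet
Title: Trait-Transcript Association Networks via DUO, Pearson and Spearman
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links transcript abundance to phenotypic traits in segregating
    plant populations. Filters an FPKM/TPM abundance matrix, combines it with
    a phenotype table, row-scales the joint matrix, discretizes it into
    matrix-wide HIGH/LOW/NEUTRAL states, and scores every transcript-trait
    pair with Pearson and Spearman correlation and with the DUO co-occurrence
    metric, a four-component similarity for extreme-state co-occurrence
    adapted from the Custom Correlation Coefficient. Builds and exports the
    resulting association networks, compares them edge-by-edge and per trait,
    and includes a synthetic-data generator that plants linear, monotone and
    extreme-quartile block associations with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
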