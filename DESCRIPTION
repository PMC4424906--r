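Package: tsnetalign
Title: Tissue-Specific Interaction Networks and Differential Local Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds tissue- and tumor-specific protein-protein interaction
    (TS-PPI) networks by integrating heterogeneous interaction and expression
    datasets into a global gene-interaction network with per-edge average
    weights and dataset coverage, and unified per-gene expression scores.
    Extracts conserved subnetworks that maximize cross-network expression
    divergence with a stochastic seed-and-extend multiple local aligner
    driven by Gibbs sampling, scored by expression log-fold change and an
    index of structural conservation.  Includes bit-exact readers and
    writers for the tool's tab-delimited formats, a synthetic benchmark
    generator with planted differential subnetworks, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    limma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
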