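Package: mirmod
Title: Network-Based Discovery of Pathway Modules Co-Regulated by miRNA Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies signaling-pathway modules that are co-regulated by a
    set of disease-associated microRNAs. For each miRNA the package builds an
    interaction network over its tissue-expressed target genes, extracts the
    largest connected component, peels nodes in order of combined (degree plus
    betweenness) centrality until the component-decay curve plateaus, and
    treats the removed nodes as key genes. Key genes are tested for pathway
    overrepresentation (hypergeometric with Benjamini-Hochberg control), the
    resulting miRNA-pathway bipartite graph is mined with a greedy
    maximal-coverage search for shared modules, and module significance is
    assessed by Monte Carlo resampling of random miRNA sets. A node-ejection
    consistency test and a self-contained synthetic-data generator with
    planted co-regulation structure are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
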