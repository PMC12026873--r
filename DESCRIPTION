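Package: netpharm
Title: Network Pharmacology Pipeline for Compound-Target-Disease Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested network-pharmacology workflow linking a
    natural product's compounds to disease genes: rule-based oral
    bioavailability screening, ligand-similarity (similarity-ensemble)
    target prediction with Z-score background calibration, two-group
    differential expression with fold-change and p-value filters,
    target intersection, bipartite compound-target and protein-protein
    interaction network centrality analysis, and hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction. A synthetic
    data generator with known ground truth replaces web databases so
    every stage is verifiable offline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
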