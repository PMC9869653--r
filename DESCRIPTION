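Package: netRx
Title: Network-Based Personalized Drug Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Personalized prioritization of candidate drugs for a single
    tumor sample on a protein interaction network (PIN) extended with drug
    nodes. Two scorers are provided: a distance-based method combining
    per-gene driverness probabilities with shortest-path hop distances
    between drugs and altered genes, and a propagation method that spreads
    driverness scores over the Laplacian-normalized extended network via a
    random walk with restart. Includes loaders for STRING-style edge lists
    and DGIdb-style drug-target tables, merging of drugs with identical
    target sets, tie-aware top-n selection, clinical drug-tier evaluation
    utilities, and a seeded synthetic fixture generator so the full
    pipeline runs end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
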