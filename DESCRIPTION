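Package: phylogd
Title: Gene-Duplication Mapping, Duplication-Burst Detection, and
    Phylogenetic Coincidence Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Phylotranscriptomic analysis of gene duplications on a species
    phylogeny. Maps duplication events from gene trees onto a reference
    species tree by LCA reconciliation with bootstrap-support filtering,
    classifies duplications by subclade retention pattern (ABAB versus
    partial), tallies per-node duplication statistics, and calls clustered
    gene-duplication bursts as candidate whole-genome duplications.
    Corroborates bursts with Nei-Gojobori synonymous-divergence (Ks)
    estimation for paralog pairs and kernel-density peak detection, and
    tests coincidence between duplication bursts, diversification-rate
    shifts, and trait transitions with a randomized-placement permutation
    test. Includes a birth-death gene-family simulator with injectable
    whole-genome duplications and synonymous-site sequence evolution that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
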