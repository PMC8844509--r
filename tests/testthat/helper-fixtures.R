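# Shared fixtures: small species trees and gene-tree builders.

stree4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);", "species")
stree3 <- function() parse_newick("((A:1,B:1):1,C:2);", "species")

# 8 species, ultrametric depth 1: the study-scale tree used by the
# simulation-based checks.  The WGD injection point used throughout is the
# MRCA of E..H.
stree8 <- function() {
  parse_newick(paste0(
    "(((A:0.2,B:0.2):0.3,(C:0.2,D:0.2):0.3):0.5,",
    "((E:0.2,F:0.2):0.3,(G:0.2,H:0.2):0.3):0.5);"), "species")
}

# deterministic ultrametric species tree with n tips labeled S1..Sn
balanced_stree <- function(n, depth = 1, seed = 2024) {
  set.seed(seed)
  phy <- ape::rcoal(n)
  phy$tip.label <- paste0("S", seq_len(n))
  phy$edge.length <- phy$edge.length / max(ape::node.depth.edgelength(phy)) * depth
  as_species_tree(phy)
}

# deterministic random rooted tree with k internal nodes (k+1 tips)
rtree_internal <- function(k, seed = 1) {
  set.seed(seed)
  phy <- ape::rtree(k + 1)
  phy$tip.label <- paste0("S", seq_len(k + 1))
  as_species_tree(phy)
}

gene_tree <- function(newick) parse_newick(newick, "gene")
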