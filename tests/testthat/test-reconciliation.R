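test_that("lca_map reproduces hand reconciliations", {
  st <- stree3()   # A=1 B=2 C=3 root=4 AB=5

  # congruent single-copy tree: identity on corresponding nodes
  gt <- gene_tree("((A|1,B|1)90,C|1)90;")
  m <- lca_map(gt, st)
  expect_equal(m[1:3], c(1L, 2L, 3L))
  expect_equal(m[4], 4L)   # gene root -> species root
  expect_equal(m[5], 5L)   # (A,B) clade -> MRCA(A,B)

  # ((A|1,A|2),B|1): within-species clade maps to the tip
  gt <- gene_tree("((A|1,A|2)90,B|1)90;")
  m <- lca_map(gt, st)
  expect_equal(m[5], 1L)   # (A|1,A|2) -> tip A
  expect_equal(m[4], 5L)   # root -> MRCA(A,B)

  # ((A|1,B|1),(A|2,B|2)): both internals and root -> MRCA(A,B)
  gt <- gene_tree("((A|1,B|1)90,(A|2,B|2)90)90;")
  m <- lca_map(gt, st)
  expect_equal(unname(m[5:7]), c(5L, 5L, 5L))
})

test_that("lca_map is monotone along every gene-tree edge", {
  st <- stree8()
  cfg <- sim_config(st, n_families = 40, dup_rate = 0.3, loss_rate = 0.15,
                    seed = 5)
  sim <- simulate_gene_families(cfg)
  anc <- phylogd:::.parent_vec(st)
  is_anc_or_eq <- function(a, b) {       # a ancestor-or-equal of b?
    while (b != 0L) { if (a == b) return(TRUE); b <- anc[b] }
    FALSE
  }
  for (gt in sim$gene_trees) {
    if (!inherits(gt, "phylo")) next
    m <- lca_map(gt, st)
    for (i in seq_len(nrow(gt$edge)))
      expect_true(is_anc_or_eq(m[gt$edge[i, 1]], m[gt$edge[i, 2]]))
  }
})

test_that("duplications are detected, filtered and classified", {
  st <- stree3()
  # one ABAB duplication at MRCA(A,B), support = min of child supports
  gt <- gene_tree("((A|1,B|1)95,(A|2,B|2)95)100;")
  ev <- detect_duplications(gt, st, min_support = 50)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$species_node, 5L)
  expect_equal(ev$support, 95)
  expect_equal(ev$type, "ABAB")

  # low support on one child branch removes the event
  gt <- gene_tree("((A|1,B|1)40,(A|2,B|2)95)100;")
  expect_equal(nrow(detect_duplications(gt, st, min_support = 50)), 0L)
  expect_equal(nrow(detect_duplications(gt, st, min_support = 40)), 1L)

  # congruent one-copy-per-species tree: no duplications
  gt <- gene_tree("((A|1,B|1)99,C|1)99;")
  expect_equal(nrow(detect_duplications(gt, st, min_support = 0)), 0L)

  # within-species paralogs: tip type
  gt <- gene_tree("((A|1,A|2)80,B|1)99;")
  ev <- detect_duplications(gt, st, min_support = 50)
  expect_equal(ev$species_node, 1L)
  expect_equal(ev$type, "tip")
})

test_that("tip children carry support 100", {
  st <- stree3()
  gt <- gene_tree("((A|1,A|2)80,B|1)99;")
  ev <- detect_duplications(gt, st, min_support = 99)
  # duplication node (A|1,A|2): children are tips -> support 100, retained
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$support, 100)
})

test_that("missing internal support fails events by default, passes on request", {
  st <- stree3()
  gt <- gene_tree("((A|1,B|1),(A|2,B|2))100;")   # children unsupported
  expect_equal(nrow(detect_duplications(gt, st, 50)), 0L)
  ev <- detect_duplications(gt, st, 50, missing_support = "pass")
  expect_equal(nrow(ev), 1L)
})

test_that("classify_duplication implements the ABAB definition", {
  st <- stree4()   # A=1..D=4, root=5, AB=6, CD=7
  expect_equal(classify_duplication(c("A", "B"), c("A", "B"), 6L, st), "ABAB")
  expect_equal(classify_duplication(c("A", "B"), c("A"), 6L, st), "partial")
  expect_equal(classify_duplication("A", "A", 1L, st), "tip")
  # spanning the root
  expect_equal(classify_duplication(c("A", "C"), c("B", "D"), 5L, st), "ABAB")
  expect_equal(classify_duplication(c("A", "C"), c("A", "B"), 5L, st), "partial")
})

test_that("polytomous gene nodes are never duplications themselves", {
  st <- stree3()
  gt <- gene_tree("(A|1,A|2,B|1)90;")   # root trifurcation, maps to MRCA(A,B)
  ev <- detect_duplications(gt, st, 0)
  expect_equal(nrow(ev), 0L)
  # but a binary duplication below a polytomy is found
  gt <- gene_tree("((A|1,A|2)90,B|1,C|1)90;"
  )
  ev <- detect_duplications(gt, st, 50)
  expect_equal(ev$species_node, 1L)
})

test_that("outgroup rooting recovers the outgroup split and skips hopeless trees", {
  st <- stree3()
  gt <- ape::unroot(gene_tree("((A|1,B|1)88,C|o1)90;"))
  rooted <- root_by_outgroup(as_gene_tree(gt), "C")
  sp <- species_of_gene(rooted$tip.label)
  kids <- phylogd:::.children_list(rooted)[[length(rooted$tip.label) + 1L]]
  sides <- lapply(kids, function(k)
    unique(sp[phylogd:::.clade_tip_ids(rooted)[[k]]]))
  expect_true(any(vapply(sides, function(s) identical(s, "C"), logical(1))))

  # already rooted with outgroup sister: unchanged split
  gt2 <- gene_tree("((A|1,B|1)88,C|o1)90;")
  rooted2 <- root_by_outgroup(gt2, "C")
  expect_setequal(clade_tips(rooted2, mrca_node(rooted2, c("A|1", "B|1"))),
                  c("A|1", "B|1"))

  expect_error(root_by_outgroup(gene_tree("((A|1,B|1)9,(A|2,B|2)9)9;"), "C"),
               class = "phylogd_unrootable")
})

test_that("non-monophyletic outgroups root at the best-matching bipartition", {
  st <- stree4()
  # outgroup species O appears twice, not sister: best split still isolates
  # the larger O-containing side
  gt <- as_gene_tree(ape::unroot(
    gene_tree("(((O|1,A|1)50,B|1)50,(O|2,C|1)50)50;")))
  rooted <- root_by_outgroup(gt, "O")
  expect_true(ape::is.rooted(rooted))
  expect_equal(sort(rooted$tip.label), sort(gt$tip.label))
})

test_that("per-node statistics tally counts, ratios and relevance", {
  st <- stree3()
  gts <- list(
    t1 = gene_tree("((A|1,B|1)95,(A|2,B|2)95)100;"),  # ABAB dup at AB
    t2 = gene_tree("((A|1,B|1)95,C|1)95;"),            # no dup
    t3 = gene_tree("(((A|1,B|1)95,(A|2,B|2)95)100,C|1)95;"))
  gd <- map_duplications(gts, st, min_support = 50)
  ns <- gd$node_stats
  ab <- ns[ns$node == 5L, ]
  expect_equal(ab$gd_count, 2L)
  expect_equal(ab$abab_count, 2L)
  expect_equal(ab$relevant_tree_count, 3L)   # all trees span both A and B
  expect_equal(ab$trees_with_gd, 2L)
  expect_equal(ab$gd_ratio, 2 / 3)
  # conservation: per-node counts sum to total retained events
  expect_equal(sum(ns$gd_count), nrow(gd$events))
  # undefined ratio where no tree is relevant (no tree has 2 C copies)
  expect_true(is.na(ns$gd_ratio[ns$node == 3L]))
  expect_equal(ns$relevant_tree_count[ns$node == 3L], 0L)
})

test_that("multiple duplications in one tree count once in the ratio numerator", {
  st <- stree3()
  gts <- list(t1 = gene_tree(
    "(((A|1,B|1)95,(A|2,B|2)95)100,((A|3,B|3)95,(A|4,B|4)95)100)100;"))
  gd <- map_duplications(gts, st, min_support = 50)
  ab <- gd$node_stats[gd$node_stats$node == 5L, ]
  expect_equal(ab$gd_count, 3L)          # three ABAB duplications at AB
  expect_equal(ab$trees_with_gd, 1L)
  expect_equal(ab$gd_ratio, 1)
})

test_that("node statistics equal the simulator's ground-truth tally", {
  st <- stree8()
  wgd_node <- mrca_node(st, c("E", "H"))
  cfg <- sim_config(st, n_families = 60, dup_rate = 0.1, loss_rate = 0,
                    wgd = data.frame(node = wgd_node, retention = 0.7),
                    seed = 11)
  sim <- simulate_gene_families(cfg)
  gd <- map_duplications(sim$gene_trees, st, min_support = 50)
  truth <- sim$truth[sim$truth$observable, ]
  # with no loss, detected (family, node) multiset == truth multiset
  det <- table(factor(gd$events$species_node,
                      levels = seq_len(length(st$tip.label) + st$Nnode)))
  tru <- table(factor(truth$map_node,
                      levels = seq_len(length(st$tip.label) + st$Nnode)))
  expect_equal(as.integer(det), as.integer(tru))
  # and per-node ABAB classes agree
  det_ab <- with(gd$events, table(factor(species_node)[type == "ABAB"]))
  tru_ab <- with(truth, table(factor(map_node)[dup_class == "ABAB"]))
  expect_equal(as.integer(det_ab), as.integer(tru_ab))
})

test_that("duplication-free simulations yield zero events everywhere", {
  st <- stree8()
  cfg <- sim_config(st, n_families = 30, dup_rate = 0, loss_rate = 0.1,
                    seed = 3)
  sim <- simulate_gene_families(cfg)
  gd <- map_duplications(sim$gene_trees, st, min_support = 0)
  expect_equal(nrow(gd$events), 0L)
  expect_true(all(gd$node_stats$gd_count == 0L))
})
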