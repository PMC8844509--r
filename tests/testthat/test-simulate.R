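test_that("a rate-free process degenerates to the species tree", {
  st <- stree8()
  cfg <- sim_config(st, n_families = 5, dup_rate = 0, loss_rate = 0, seed = 1)
  sim <- simulate_gene_families(cfg)
  for (gt in sim$gene_trees) {
    expect_s3_class(gt, "phylo")
    sp <- sort(species_of_gene(gt$tip.label))
    expect_equal(sp, sort(st$tip.label))       # one copy per species
    # topology congruent: every species-tree clade appears
    for (v in (length(st$tip.label) + 1L):(length(st$tip.label) + st$Nnode)) {
      want <- sort(clade_tips(st, v))
      got <- mrca_node(gt, gt$tip.label[match(want,
                                              species_of_gene(gt$tip.label))])
      expect_setequal(sort(unique(species_of_gene(clade_tips(gt, got)))), want)
    }
  }
  expect_equal(nrow(sim$truth), 0L)
})

test_that("full retention with no turnover gives one ABAB duplication per family", {
  st <- stree8()
  wgd_node <- mrca_node(st, c("E", "H"))
  cfg <- sim_config(st, n_families = 25, dup_rate = 0, loss_rate = 0,
                    wgd = data.frame(node = wgd_node, retention = 1),
                    seed = 2)
  sim <- simulate_gene_families(cfg)
  expect_equal(nrow(sim$truth), 25L)
  expect_true(all(sim$truth$type == "wgd"))
  expect_true(all(sim$truth$observable))
  expect_true(all(sim$truth$map_node == wgd_node))
  expect_true(all(sim$truth$dup_class == "ABAB"))
  # and the reconciliation module recovers exactly these events
  gd <- map_duplications(sim$gene_trees, st, min_support = 50)
  expect_equal(nrow(gd$events), 25L)
  expect_true(all(gd$events$species_node == wgd_node))
  expect_true(all(gd$events$type == "ABAB"))
})

test_that("copy numbers grow at the branching-process rate", {
  st <- parse_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);", "species")
  lambda <- 0.1
  cfg <- sim_config(st, n_families = 1000, dup_rate = lambda, loss_rate = 0,
                    seed = 3)
  sim <- simulate_gene_families(cfg)
  copies <- vapply(sim$gene_trees, function(gt) {
    sp <- species_of_gene(if (inherits(gt, "phylo")) gt$tip.label else gt)
    sum(sp == "A")
  }, numeric(1))
  expected <- exp(lambda * 1.0)                 # root-to-tip path length 1
  sdev <- stats::sd(copies) / sqrt(length(copies))
  expect_lt(abs(mean(copies) - expected), 3 * sdev + 1e-8)
})

test_that("background duplications map to the branch where they occurred", {
  st <- stree8()
  cfg <- sim_config(st, n_families = 100, dup_rate = 0.3, loss_rate = 0,
                    seed = 4)
  sim <- simulate_gene_families(cfg)
  truth <- sim$truth
  expect_true(all(truth$observable))            # no loss: everything survives
  expect_true(all(truth$map_node == truth$species_node))
  # exact bookkeeping: detected multiset == truth multiset per node
  gd <- map_duplications(sim$gene_trees, st, min_support = 50)
  nn <- length(st$tip.label) + st$Nnode
  expect_equal(
    as.integer(table(factor(gd$events$species_node, levels = 1:nn))),
    as.integer(table(factor(truth$map_node, levels = 1:nn))))
})

test_that("WGD recall at the injection node degrades monotonically with loss", {
  st <- stree8()
  wgd_node <- mrca_node(st, c("E", "H"))
  recall <- numeric(3)
  mus <- c(0, 0.1, 0.3)
  for (i in seq_along(mus)) {
    cfg <- sim_config(st, n_families = 200, dup_rate = 0, loss_rate = mus[i],
                      wgd = data.frame(node = wgd_node, retention = 0.6),
                      seed = 5)
    sim <- simulate_gene_families(cfg)
    gd <- map_duplications(sim$gene_trees, st, min_support = 50)
    n_true <- sum(sim$truth$type == "wgd" & sim$truth$observable)
    n_hit <- sum(gd$events$species_node == wgd_node)
    recall[i] <- n_hit / n_true
  }
  expect_gte(recall[1], 0.95)
  expect_gte(recall[1], recall[2])
  expect_gt(recall[2], recall[3])
})

test_that("simulations are bit-reproducible from (config, seed)", {
  st <- stree8()
  cfg <- sim_config(st, n_families = 10, dup_rate = 0.2, loss_rate = 0.1,
                    wgd = data.frame(node = 13L, retention = 0.5), seed = 6)
  s1 <- simulate_gene_families(cfg)
  s2 <- simulate_gene_families(cfg)
  expect_identical(lapply(s1$gene_trees, write_newick_safe <- function(gt)
    if (inherits(gt, "phylo")) write_newick(gt) else gt),
    lapply(s2$gene_trees, write_newick_safe))
  expect_identical(s1$truth, s2$truth)
  # single families regenerate batch members exactly
  one <- simulate_gene_tree(cfg, 7)
  batch7 <- s1$truth[s1$truth$family == 7, , drop = FALSE]
  rownames(batch7) <- NULL
  expect_identical(one$truth, batch7)
})

test_that("sequence evolution is synonymous-only and rate-faithful", {
  gt <- parse_newick("(a|1:0.2,a|2:0.2)100;", "gene")
  # zero rate: identical sequences
  s0 <- simulate_codon_sequences(gt, syn_rate = 0, n_codons = 100, seed = 1)
  expect_identical(s0[["a|1"]], s0[["a|2"]])
  # no stops in any frame-0 translation
  tb <- phylogd:::.codon_tables()
  for (i in 1:10) {
    s <- simulate_codon_sequences(gt, syn_rate = 2, n_codons = 120,
                                  seed = 40 + i)
    for (q in s) {
      cods <- substring(q, seq(1, nchar(q), 3), seq(3, nchar(q), 3))
      expect_false(any(tb$is_stop[cods]))
    }
  }
  # expected Ks ~ syn_rate * total time within 10% over replicates
  ksbar <- mean(vapply(1:200, function(i) {
    s <- simulate_codon_sequences(gt, syn_rate = 0.5, n_codons = 200,
                                  seed = 900 + i)
    ng86_pair(s[["a|1"]], s[["a|2"]])$Ks
  }, numeric(1)))
  expect_lt(abs(ksbar - 0.2) / 0.2, 0.10)
  expect_warning(simulate_codon_sequences(gt, 1, 20, seed = 1), "variance")
})

test_that("planted feature sets honour the requested association", {
  st <- balanced_stree(17)   # 16 internal nodes
  fs <- plant_feature_sets(st, "full", 3, seed = 1)
  expect_equal(coincidence_count(fs$a, fs$b, st), 3L)
  fs <- plant_feature_sets(st, "partial", 4, p = 0.5, seed = 2)
  expect_gte(coincidence_count(fs$a, fs$b, st), 2L)
  expect_error(plant_feature_sets(st, "none", 40, seed = 3), "exceeds")

  # independence: mean coincidence ~= k^2 / n_internal
  k <- 3; n <- 16; n_draw <- 10000
  set.seed(9)
  cc <- vapply(seq_len(n_draw), function(i) {
    f <- plant_feature_sets(st, "none", k)
    coincidence_count(f$a, f$b, st)
  }, numeric(1))
  expected <- k^2 / n
  sdev <- stats::sd(cc) / sqrt(n_draw)
  expect_lt(abs(mean(cc) - expected), 3 * sdev)
})

test_that("extinct families are reported, not silently dropped", {
  st <- stree8()
  # overwhelming loss: most families die even with retries
  cfg <- sim_config(st, n_families = 12, dup_rate = 0, loss_rate = 30,
                    seed = 7)
  sim <- simulate_gene_families(cfg)
  expect_length(sim$gene_trees, 12L)
  expect_true(any(vapply(sim$gene_trees, is.null, logical(1))))
})
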