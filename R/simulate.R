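# Birth-death gene-family simulator on a species tree, with injectable
# whole-genome duplications and ground-truth bookkeeping.
#
# Each family starts as a single lineage at the species-tree root.  Within a
# branch every gene lineage independently duplicates at rate dup_rate and
# dies at rate loss_rate (events/lineage/time).  At a speciation node every
# surviving lineage enters both descendant branches.  At a node carrying a
# WGD, every arriving lineage duplicates with the retention probability
# before speciating, so both copies descend into both child lineages -- the
# ABAB pattern, eroded only by subsequent losses.  Losses are simulated as
# lineage death within branches (not post-hoc pruning), which is what
# produces realistic partial (non-ABAB) retention patterns.

#' Simulation configuration
#'
#' @param species_tree rooted species tree with branch lengths in time
#'   units.
#' @param n_families number of gene families to simulate.
#' @param dup_rate background duplication rate (events/lineage/time).
#' @param loss_rate loss rate (events/lineage/time).
#' @param wgd optional WGD specification: a data frame (or list coercible to
#'   one) with columns `node` (species-tree node id) and `retention`
#'   (per-copy retention probability in `[0, 1]`).
#' @param support support model for gene-tree internal nodes: a single value
#'   (constant support) or a length-2 integer range for uniform jitter.
#' @param seed master seed; each family uses its own seed derived from it,
#'   so [simulate_gene_tree()] regenerates any single family exactly.
#' @param root_stem length of a stem branch above the species-tree root
#'   (default 0: no duplications can predate the root).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(species_tree, n_families = 100L, dup_rate = 0,
                       loss_rate = 0, wgd = NULL, support = 100,
                       seed = 1L, root_stem = 0) {
  stopifnot(inherits(species_tree, "phylo"), dup_rate >= 0, loss_rate >= 0,
            n_families >= 1L, root_stem >= 0)
  if (is.null(species_tree$edge.length))
    stop("species tree needs branch lengths (time units)", call. = FALSE)
  if (!is.null(wgd)) {
    wgd <- as.data.frame(wgd)
    stopifnot(all(c("node", "retention") %in% names(wgd)),
              all(wgd$retention >= 0 & wgd$retention <= 1))
    nmax <- length(species_tree$tip.label) + species_tree$Nnode
    if (any(wgd$node < 1L | wgd$node > nmax))
      stop("WGD node id outside the species tree", call. = FALSE)
  }
  if (length(support) == 1L) support <- c(support, support)
  stopifnot(length(support) == 2L, support[1L] <= support[2L],
            all(support >= 0 & support <= 100))
  structure(list(species_tree = species_tree, n_families = as.integer(n_families),
                 dup_rate = dup_rate, loss_rate = loss_rate, wgd = wgd,
                 support = support, seed = as.integer(seed),
                 root_stem = root_stem),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Gene-family simulation config:", x$n_families, "families on",
      length(x$species_tree$tip.label), "species\n")
  cat("  dup rate", x$dup_rate, "| loss rate", x$loss_rate,
      "| seed", x$seed, "\n")
  if (!is.null(x$wgd))
    cat("  WGD at node(s)", paste(x$wgd$node, collapse = ","),
        "retention", paste(x$wgd$retention, collapse = ","), "\n")
  invisible(x)
}

# simulate one family; returns list(tree = phylo | tip-label string | NULL,
# truth = data.frame of events).  Assumes the RNG is already seeded.
.sim_family <- function(config, fam) {
  stree <- config$species_tree
  ntip <- length(stree$tip.label)
  root <- ntip + 1L
  kids <- .children_list(stree)
  stem <- numeric(ntip + stree$Nnode)
  stem[stree$edge[, 2L]] <- stree$edge.length
  wgd_r <- numeric(ntip + stree$Nnode)
  if (!is.null(config$wgd)) wgd_r[config$wgd$node] <- config$wgd$retention
  lam <- config$dup_rate; mu <- config$loss_rate

  env <- new.env(parent = emptyenv())
  env$events <- list()
  env$copy <- 0L

  new_event <- function(node, type, time) {
    id <- length(env$events) + 1L
    env$events[[id]] <- list(id = id, node = node, type = type, time = time,
                             observable = FALSE, s1 = NULL, s2 = NULL)
    id
  }
  dup_record <- function(eid, left, right, time) {
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) return(right)
    if (is.null(right)) return(left)
    ev <- env$events[[eid]]
    ev$observable <- TRUE
    ev$s1 <- unique(left$spset); ev$s2 <- unique(right$spset)
    env$events[[eid]] <- ev
    list(time = time, children = list(left, right),
         spset = c(left$spset, right$spset), label = NULL)
  }

  at_node_core <- function(v, t) {
    if (v <= ntip) {
      env$copy <- env$copy + 1L
      lab <- paste0(stree$tip.label[v], "|f", fam, "c", env$copy)
      return(list(time = t, children = NULL, spset = stree$tip.label[v],
                  label = lab))
    }
    ch <- kids[[v]]
    sub <- lapply(ch, function(c1) evolve_branch(c1, t, stem[c1]))
    sub <- sub[!vapply(sub, is.null, logical(1))]
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L) return(sub[[1L]])
    node <- list(time = t, children = sub, label = NULL,
                 spset = unlist(lapply(sub, `[[`, "spset")))
    node
  }

  at_node <- function(v, t) {
    if (wgd_r[v] > 0 && stats::runif(1) < wgd_r[v]) {
      eid <- new_event(v, "wgd", t)
      left <- at_node_core(v, t)
      right <- at_node_core(v, t)
      return(dup_record(eid, left, right, t))
    }
    at_node_core(v, t)
  }

  evolve_branch <- function(v, t, remaining) {
    rate <- lam + mu
    repeat {
      if (rate == 0) return(at_node(v, t + remaining))
      w <- stats::rexp(1, rate)
      if (w >= remaining) return(at_node(v, t + remaining))
      t <- t + w; remaining <- remaining - w
      if (stats::runif(1) < lam / rate) {
        eid <- new_event(v, "background", t)
        left <- evolve_branch(v, t, remaining)
        right <- evolve_branch(v, t, remaining)
        return(dup_record(eid, left, right, t))
      }
      return(NULL)  # loss
    }
  }

  rec <- evolve_branch(root, 0, config$root_stem)

  truth <- .events_to_truth(env$events, stree, fam)
  list(rec = rec, truth = truth)
}

.events_to_truth <- function(events, stree, fam) {
  if (length(events) == 0L)
    return(data.frame(family = integer(0), event = integer(0),
                      species_node = integer(0), type = character(0),
                      time = numeric(0), observable = logical(0),
                      map_node = integer(0), dup_class = character(0),
                      stringsAsFactors = FALSE))
  mrca2 <- .mrca_fun(stree)
  set_mrca <- function(spp) {
    ids <- match(unique(spp), stree$tip.label)
    Reduce(mrca2, ids)
  }
  rows <- lapply(events, function(ev) {
    map <- NA_integer_; cls <- NA_character_
    if (ev$observable) {
      map <- set_mrca(c(ev$s1, ev$s2))
      cls <- classify_duplication(ev$s1, ev$s2, map, stree)
    }
    data.frame(family = fam, event = ev$id, species_node = ev$node,
               type = ev$type, time = ev$time, observable = ev$observable,
               map_node = map, dup_class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# convert the recursive record to a phylo (>= 2 tips), a bare tip label
# (single survivor) or NULL (extinct)
.record_to_tree <- function(rec, support) {
  if (is.null(rec)) return(NULL)
  if (is.null(rec$children)) return(rec$label)
  tips <- character(0); tip_time <- numeric(0)
  count <- function(r) {
    if (is.null(r$children)) {
      tips <<- c(tips, r$label); tip_time <<- c(tip_time, r$time)
      return(invisible(NULL))
    }
    for (ch in r$children) count(ch)
  }
  count(rec)
  ntip <- length(tips)
  env <- new.env(parent = emptyenv())
  env$tip_i <- 0L; env$node_i <- ntip + 1L
  env$edges <- matrix(0L, 0L, 2L); env$elen <- numeric(0)
  assign_ids <- function(r) {
    if (is.null(r$children)) {
      env$tip_i <- env$tip_i + 1L
      return(env$tip_i)
    }
    my <- env$node_i; env$node_i <- env$node_i + 1L
    for (ch in r$children) {
      cid <- assign_ids(ch)
      env$edges <- rbind(env$edges, c(my, cid))
      env$elen <- c(env$elen, ch$time - r$time)
    }
    my
  }
  assign_ids(rec)
  nnode <- env$node_i - ntip - 1L
  sup <- if (support[1L] == support[2L]) rep(support[1L], nnode)
  else sample(seq(support[1L], support[2L]), nnode, replace = TRUE)
  phy <- structure(list(edge = env$edges, tip.label = tips,
                        edge.length = env$elen, Nnode = nnode,
                        node.label = as.character(sup)),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  as_gene_tree(phy)
}

# per-family seed: the family-th draw of the seed stream started at the
# master seed, so family i is reproducible in isolation and families are
# decorrelated across nearby master seeds
.family_seed <- function(seed, family) {
  set.seed(seed)
  sample.int(2147483646L, family)[family]
}

#' Simulate one gene family
#'
#' Regenerates family `family` of [simulate_gene_families()] exactly (the
#' family seed is the `family`-th draw of a seed stream derived from
#' `config$seed`).  Extinct attempts are retried up to 100 times; a family
#' that never survives is returned with `tree = NULL`.
#'
#' @param config a [sim_config()].
#' @param family family index (1-based).
#' @return list with `tree` (a gene tree, a bare tip label for single-copy
#'   families, or `NULL`), and `truth`, the per-event ground-truth table:
#'   `family`, `event`, `species_node` (branch where the event occurred),
#'   `type` (`"wgd"`/`"background"`), `time`, `observable` (both copies
#'   left survivors), `map_node` (species node an LCA reconciliation should
#'   recover, from the simulator's own survivor bookkeeping) and
#'   `dup_class` (`"ABAB"`/`"partial"`/`"tip"`).
#' @export
simulate_gene_tree <- function(config, family) {
  stopifnot(inherits(config, "sim_config"))
  family <- as.integer(family)
  set.seed(.family_seed(config$seed, family))
  for (attempt in seq_len(100L)) {
    res <- .sim_family(config, family)
    if (!is.null(res$rec)) {
      rownames(res$truth) <- NULL
      return(list(tree = .record_to_tree(res$rec, config$support),
                  truth = res$truth))
    }
  }
  list(tree = NULL,
       truth = .events_to_truth(list(), config$species_tree, family))
}

#' Simulate a collection of gene families with ground truth
#'
#' @param config a [sim_config()].
#' @return object of class `gd_sim`: `gene_trees` (named list, one entry per
#'   family: a gene tree, a bare tip label, or `NULL` if the family went
#'   extinct in all attempts), `truth` (row-bound per-event tables of
#'   [simulate_gene_tree()], observable events only have `map_node` set),
#'   and the `config`.
#' @export
simulate_gene_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  trees <- vector("list", config$n_families)
  truth <- vector("list", config$n_families)
  for (i in seq_len(config$n_families)) {
    res <- simulate_gene_tree(config, i)
    trees[i] <- list(res$tree)          # [[<- would drop NULL (extinct) entries
    truth[[i]] <- res$truth
  }
  names(trees) <- sprintf("fam%04d", seq_len(config$n_families))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(gene_trees = trees, truth = truth, config = config),
            class = "gd_sim")
}

#' @export
print.gd_sim <- function(x, ...) {
  n <- length(x$gene_trees)
  ext <- sum(vapply(x$gene_trees, is.null, logical(1)))
  single <- sum(vapply(x$gene_trees, is.character, logical(1)))
  obs <- x$truth[x$truth$observable, , drop = FALSE]
  cat("Simulated gene families:", n, "(", ext, "extinct,", single,
      "single-copy )\n")
  cat("  observable duplication events:", nrow(obs),
      "(", sum(obs$type == "wgd"), "WGD-derived )\n")
  invisible(x)
}

#' Simulate aligned codon sequences along a gene tree
#'
#' The root sequence is drawn uniformly from the 61 stop-free codons.
#' Evolution is synonymous-only: on each branch the substitution count is
#' Poisson(branch length x `syn_rate` x synonymous sites at branch start),
#' and each substitution picks a codon with probability proportional to its
#' number of synonymous single-nucleotide changes, then one such change
#' uniformly.  Translations therefore never gain stops and the alignment is
#' exact by construction; Ka on simulated pairs is 0.
#'
#' @param gtree a gene tree with branch lengths in time units (a bare
#'   tip-label string yields a single random sequence).
#' @param syn_rate substitutions per synonymous site per time unit.
#' @param n_codons sequence length in codons (a warning is issued below 50,
#'   where Ks estimates get noisy).
#' @param seed optional integer seed.
#' @return named character vector of aligned CDS, one per tip.
#' @export
simulate_codon_sequences <- function(gtree, syn_rate, n_codons,
                                     seed = NULL) {
  stopifnot(syn_rate >= 0, n_codons >= 1)
  if (n_codons < 50L)
    warning("n_codons < 50: Ks estimates will have high variance")
  if (!is.null(seed)) set.seed(seed)
  tb <- .codon_tables()
  pool <- tb$codons[!tb$is_stop]
  root_seq <- sample(pool, n_codons, replace = TRUE)
  if (is.character(gtree) && !inherits(gtree, "phylo")) {
    out <- paste(root_seq, collapse = "")
    names(out) <- gtree
    return(out)
  }
  stopifnot(inherits(gtree, "phylo"))
  if (is.null(gtree$edge.length))
    stop("gene tree needs branch lengths (time units)", call. = FALSE)

  nsyn <- vapply(tb$syn_changes, length, integer(1))  # 3 x syn sites per codon
  ntip <- length(gtree$tip.label)
  seqs <- vector("list", ntip + gtree$Nnode)
  seqs[[ntip + 1L]] <- root_seq
  out <- character(ntip)
  e <- ape::reorder.phylo(gtree, "cladewise")$edge
  elen <- gtree$edge.length[match(paste(e[, 1L], e[, 2L]),
                                  paste(gtree$edge[, 1L], gtree$edge[, 2L]))]
  for (i in seq_len(nrow(e))) {
    s <- seqs[[e[i, 1L]]]
    w <- nsyn[s]
    S <- sum(w) / 3
    nsub <- stats::rpois(1, elen[i] * syn_rate * S)
    for (k in seq_len(nsub)) {
      j <- sample.int(n_codons, 1L, prob = w)
      nb <- tb$syn_changes[[s[j]]]
      s[j] <- if (length(nb) == 1L) nb else sample(nb, 1L)
      w[j] <- nsyn[s[j]]
    }
    if (e[i, 2L] <= ntip) out[e[i, 2L]] <- paste(s, collapse = "")
    else seqs[[e[i, 2L]]] <- s
  }
  names(out) <- gtree$tip.label
  out
}

#' Simulate sequences for every family of a simulation
#'
#' @param sim a `gd_sim` from [simulate_gene_families()].
#' @param syn_rate,n_codons see [simulate_codon_sequences()].
#' @param seed master seed (each family uses its own derived seed).
#' @return named character vector of aligned CDS over all families (tip
#'   labels are globally unique).
#' @export
simulate_family_sequences <- function(sim, syn_rate, n_codons, seed = 1L) {
  stopifnot(inherits(sim, "gd_sim"))
  out <- character(0)
  for (i in seq_along(sim$gene_trees)) {
    gt <- sim$gene_trees[[i]]
    if (is.null(gt)) next
    out <- c(out, simulate_codon_sequences(gt, syn_rate, n_codons,
                                           seed = .family_seed(seed, i)))
  }
  out
}

#' Plant a pair of feature node sets with a controlled association
#'
#' @param tree species tree.
#' @param association `"none"` (two independent uniform draws), `"full"`
#'   (B = A), or `"partial"` (B shares `ceiling(p * k_each)` nodes with A,
#'   the rest drawn uniformly from the complement).
#' @param k_each nodes per set.
#' @param p shared fraction for `association = "partial"`.
#' @param seed optional integer seed.
#' @return list with [feature_set()]s `a` and `b`.
#' @export
plant_feature_sets <- function(tree, association = c("none", "full", "partial"),
                               k_each, p = 0.5, seed = NULL) {
  association <- match.arg(association)
  elig <- eligible_nodes(tree)
  if (k_each > length(elig))
    stop("k_each exceeds the number of internal nodes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- sample(elig, k_each)
  b <- switch(association,
    none = sample(elig, k_each),
    full = a,
    partial = {
      n_shared <- ceiling(p * k_each)
      if (n_shared > k_each)
        stop("infeasible p: shared count exceeds k_each", call. = FALSE)
      rest <- setdiff(elig, a)
      if (k_each - n_shared > length(rest))
        stop("infeasible p/k: complement too small", call. = FALSE)
      c(sample(a, n_shared),
        if (k_each > n_shared) sample(rest, k_each - n_shared))
    })
  list(a = feature_set(tree, a, "A"), b = feature_set(tree, b, "B"))
}
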