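# Independent oracles used by the test suite.  These deliberately avoid the
# package's internal helpers: plain recursions and a separately written
# genetic-code table, so agreement with the implementation is informative.

# ---- brute-force LCA reconciliation --------------------------------------
# For every gene-tree node the species image is recomputed directly: the
# species set of its clade is collected by descent, and the species tree is
# scanned for the smallest clade containing that set.  A node is a
# duplication iff its image equals the image of at least one child.

oracle_clade_tips <- function(phy, v) {
  ntip <- length(phy$tip.label)
  if (v <= ntip) return(phy$tip.label[v])
  kids <- phy$edge[phy$edge[, 1] == v, 2]
  unlist(lapply(kids, function(k) oracle_clade_tips(phy, k)))
}

oracle_reconcile <- function(gtree, stree, delimiter = "|") {
  ntip_g <- length(gtree$tip.label)
  nn_g <- ntip_g + gtree$Nnode
  ntip_s <- length(stree$tip.label)
  nn_s <- ntip_s + stree$Nnode

  s_clades <- lapply(seq_len(nn_s), function(v) oracle_clade_tips(stree, v))
  gene_species <- function(labels)
    unique(sub(paste0("\\", delimiter, ".*$"), "", labels))

  image_of <- function(spset) {
    sizes <- vapply(s_clades, length, integer(1))
    cand <- which(vapply(s_clades, function(cl) all(spset %in% cl), logical(1)))
    cand[which.min(sizes[cand])]
  }
  imgs <- vapply(seq_len(nn_g), function(v)
    image_of(gene_species(oracle_clade_tips(gtree, v))), integer(1))

  rows <- list()
  for (v in seq_len(nn_g)) {
    kids <- gtree$edge[gtree$edge[, 1] == v, 2]
    if (length(kids) != 2) next
    if (!any(imgs[kids] == imgs[v])) next
    s1 <- gene_species(oracle_clade_tips(gtree, kids[1]))
    s2 <- gene_species(oracle_clade_tips(gtree, kids[2]))
    type <- if (imgs[v] <= ntip_s) "tip" else {
      sk <- stree$edge[stree$edge[, 1] == imgs[v], 2]
      A <- s_clades[[sk[1]]]
      B <- unlist(s_clades[sk[-1]])
      if (any(s1 %in% A) && any(s1 %in% B) && any(s2 %in% A) && any(s2 %in% B))
        "ABAB" else "partial"
    }
    rows[[length(rows) + 1]] <- data.frame(
      gene_node = v, species_node = imgs[v], type = type,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_node = integer(0), species_node = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# ---- exhaustive enumeration of species-labeled rooted binary topologies --
# All rooted binary trees whose leaves carry species labels drawn (with
# repetition) from `species`, with `n` leaves.  Leaves of the same species
# are exchangeable for reconciliation, so enumerating label-multisets covers
# every distinguishable instance.  Trees are nested lists; leaves are
# species strings.

enum_labeled_trees <- local({
  memo <- new.env(parent = emptyenv())
  function(counts, species) {
    key <- paste(counts, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    n <- sum(counts)
    out <- list()
    if (n == 1L) {
      out <- list(species[which(counts == 1L)])
    } else {
      splits <- expand.grid(lapply(counts, function(m) 0:m))
      for (r in seq_len(nrow(splits))) {
        k1 <- as.integer(splits[r, ])
        k2 <- counts - k1
        if (sum(k1) == 0L || sum(k2) == 0L) next
        key1 <- paste(k1, collapse = ","); key2 <- paste(k2, collapse = ",")
        if (key1 > key2) next                      # unordered split
        t1 <- enum_labeled_trees(k1, species)
        t2 <- enum_labeled_trees(k2, species)
        if (key1 == key2) {
          for (i in seq_along(t1)) for (j in i:length(t2))
            out[[length(out) + 1]] <- list(t1[[i]], t2[[j]])
        } else {
          for (i in seq_along(t1)) for (j in seq_along(t2))
            out[[length(out) + 1]] <- list(t1[[i]], t2[[j]])
        }
      }
    }
    memo[[key]] <- out
    out
  }
})

# count via the same recurrence but arithmetic only (independent of the list
# construction, used to check the enumeration is complete)
count_labeled_trees <- local({
  memo <- new.env(parent = emptyenv())
  function(counts) {
    key <- paste(counts, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    n <- sum(counts)
    tot <- 0
    if (n == 1L) tot <- 1 else {
      splits <- expand.grid(lapply(counts, function(m) 0:m))
      for (r in seq_len(nrow(splits))) {
        k1 <- as.integer(splits[r, ])
        k2 <- counts - k1
        if (sum(k1) == 0L || sum(k2) == 0L) next
        key1 <- paste(k1, collapse = ","); key2 <- paste(k2, collapse = ",")
        if (key1 > key2) next
        c1 <- count_labeled_trees(k1); c2 <- count_labeled_trees(k2)
        tot <- tot + if (key1 == key2) c1 * (c1 + 1) / 2 else c1 * c2
      }
    }
    memo[[key]] <- tot
    tot
  }
})

# nested-list tree -> gene_tree phylo with distinct per-species copy ids
nested_to_gene_tree <- function(tr) {
  counter <- new.env(parent = emptyenv())
  label <- function(sp) {
    i <- (counter[[sp]] %||% 0L) + 1L
    counter[[sp]] <- i
    paste0(sp, "|g", i)
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  tips <- character(0)
  count_tips <- function(t) {
    if (is.character(t)) { tips <<- c(tips, label(t)); return(invisible(NULL)) }
    count_tips(t[[1]]); count_tips(t[[2]])
  }
  count_tips(tr)
  ntip <- length(tips)
  env <- new.env(parent = emptyenv())
  env$tip_i <- 0L; env$node_i <- ntip + 1L
  env$edges <- matrix(0L, 0, 2)
  build <- function(t) {
    if (is.character(t)) { env$tip_i <- env$tip_i + 1L; return(env$tip_i) }
    my <- env$node_i; env$node_i <- env$node_i + 1L
    for (ch in t) {
      cid <- build(ch)
      env$edges <- rbind(env$edges, c(my, cid))
    }
    my
  }
  build(tr)
  nnode <- env$node_i - ntip - 1L
  phy <- structure(list(edge = env$edges, tip.label = tips, Nnode = nnode,
                        node.label = rep("100", nnode)),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  as_gene_tree(phy)
}

# ---- brute-force Nei-Gojobori --------------------------------------------
# Fresh genetic-code table (alphabetical base order, alphabetical codon
# construction) and direct pathway enumeration by recursive descent.

oracle_code <- local({
  code <- NULL
  function() {
    if (!is.null(code)) return(code)
    b <- c("A", "C", "G", "T")
    aa_of <- c(
      AAA="K", AAC="N", AAG="K", AAT="N", ACA="T", ACC="T", ACG="T", ACT="T",
      AGA="R", AGC="S", AGG="R", AGT="S", ATA="I", ATC="I", ATG="M", ATT="I",
      CAA="Q", CAC="H", CAG="Q", CAT="H", CCA="P", CCC="P", CCG="P", CCT="P",
      CGA="R", CGC="R", CGG="R", CGT="R", CTA="L", CTC="L", CTG="L", CTT="L",
      GAA="E", GAC="D", GAG="E", GAT="D", GCA="A", GCC="A", GCG="A", GCT="A",
      GGA="G", GGC="G", GGG="G", GGT="G", GTA="V", GTC="V", GTG="V", GTT="V",
      TAA="*", TAC="Y", TAG="*", TAT="Y", TCA="S", TCC="S", TCG="S", TCT="S",
      TGA="*", TGC="C", TGG="W", TGT="C", TTA="L", TTC="F", TTG="L", TTT="F")
    code <<- list(bases = b, aa = aa_of)
    code
  }
})

oracle_syn_sites <- function(codon) {
  cd <- oracle_code()
  s <- 0
  cv <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (nt in cd$bases) {
    if (nt == cv[pos]) next
    alt <- cv; alt[pos] <- nt
    alt <- paste(alt, collapse = "")
    if (cd$aa[[alt]] != "*" && cd$aa[[alt]] == cd$aa[[codon]]) s <- s + 1
  }
  s / 3
}

# all orderings of a set, built iteratively (insertion construction)
oracle_orders <- function(x) {
  out <- list(x[0])
  for (el in x) {
    nxt <- list()
    for (p in out) for (pos in 0:length(p))
      nxt[[length(nxt) + 1]] <- append(p, el, after = pos)
    out <- nxt
  }
  unique(out)
}

oracle_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  cd <- oracle_code()
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  paths <- oracle_orders(pos)
  step_counts <- function(ord, allow_stop) {
    cur <- v1; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- v2[p]
      a1 <- cd$aa[[paste(cur, collapse = "")]]
      a2 <- cd$aa[[paste(nxt, collapse = "")]]
      if (a2 == "*" && !allow_stop) return(NULL)
      if (a1 != "*" && a2 != "*" && a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, step_counts, allow_stop = FALSE))
  if (!length(res)) res <- lapply(paths, step_counts, allow_stop = TRUE)
  Reduce(`+`, res) / length(res)
}

oracle_ng86 <- function(a, b) {
  cd <- oracle_code()
  split3 <- function(s) {
    s <- toupper(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- split3(a); cb <- split3(b)
  stopifnot(length(ca) == length(cb))
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ok[ok] <- cd$aa[ca[ok]] != "*" & cd$aa[cb[ok]] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- c(0, 0)
  for (i in which(ca != cb)) d <- d + oracle_pair_diffs(ca[i], cb[i])
  ps <- d[1] / S; pn <- d[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[1], Nd = d[2], ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn))
}

# random stop-free in-frame sequence and a mutated partner
random_cds_pair <- function(n_codons, n_mut, seed) {
  set.seed(seed)
  cd <- oracle_code()
  pool <- names(cd$aa)[cd$aa != "*"]
  a_cod <- sample(pool, n_codons, replace = TRUE)
  b <- strsplit(paste(a_cod, collapse = ""), "")[[1]]
  for (i in sample(length(b), n_mut)) {
    repeat {
      cand <- b
      cand[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
      cod_i <- (i - 1) %/% 3
      cod <- paste(cand[(cod_i * 3 + 1):(cod_i * 3 + 3)], collapse = "")
      if (cd$aa[[cod]] != "*") { b <- cand; break }
    }
  }
  c(paste(a_cod, collapse = ""), paste(b, collapse = ""))
}

# ---- exact permutation null ----------------------------------------------
# Exact tail probability of the coincidence count when a k-subset of
# `eligible` is drawn uniformly: enumerate all C(n, k) placements.

exact_coincidence_tail <- function(fixed, eligible, k, obs) {
  combos <- utils::combn(eligible, k)
  counts <- apply(combos, 2, function(s) length(intersect(s, fixed)))
  mean(counts >= obs)
}
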