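# LCA reconciliation of gene trees against a reference species tree.
#
# A gene-tree node is a duplication iff its species-tree image (the MRCA of
# the species in its clade) equals the image of at least one of its children.
# Duplications are retained when both subtending subclades are credible:
# min(child supports) >= min_support, tips counting as support 100.

#' Root a gene tree on its outgroup
#'
#' Roots on the branch subtending the smallest clade containing all present
#' outgroup tips.  If no rooting makes the outgroup monophyletic, the branch
#' whose bipartition best matches the outgroup set (highest Jaccard overlap
#' on either side; ties broken by post-order edge index) is used.
#'
#' @param gtree a gene tree.
#' @param outgroup_species character vector of outgroup species ids.
#' @param delimiter gene-label delimiter (see [species_of_gene()]).
#' @return a rooted gene tree.
#' @export
root_by_outgroup <- function(gtree, outgroup_species, delimiter = "|") {
  stopifnot(inherits(gtree, "phylo"))
  sp <- species_of_gene(gtree$tip.label, delimiter)
  og <- gtree$tip.label[sp %in% outgroup_species]
  if (length(og) == 0L)
    stop(structure(class = c("phylogd_unrootable", "error", "condition"),
                   list(message = "no outgroup tip present in gene tree",
                        call = sys.call(-1))))
  if (length(og) == length(gtree$tip.label))
    stop(structure(class = c("phylogd_unrootable", "error", "condition"),
                   list(message = "all tips are outgroup; cannot root",
                        call = sys.call(-1))))
  phy <- ape::unroot(gtree)
  rooted <- tryCatch(
    ape::root(phy, outgroup = og, resolve.root = TRUE),
    error = function(e) NULL
  )
  if (is.null(rooted)) {
    # outgroup not monophyletic under any rooting: score every bipartition
    sides <- .clade_tip_ids(phy)
    og_ids <- match(og, phy$tip.label)
    ntip <- length(phy$tip.label)
    e <- ape::reorder.phylo(phy, "postorder")$edge
    best <- -Inf; best_side <- NULL
    for (i in seq_len(nrow(e))) {
      below <- sides[[e[i, 2L]]]
      for (s in list(below, setdiff(seq_len(ntip), below))) {
        if (length(s) == 0L || length(s) == ntip) next
        j <- length(intersect(og_ids, s)) / length(union(og_ids, s))
        if (j > best) { best <- j; best_side <- s }
      }
    }
    rooted <- ape::root(phy, outgroup = phy$tip.label[best_side],
                        resolve.root = TRUE)
  }
  as_gene_tree(rooted)
}

#' LCA map of a gene tree onto the species tree
#'
#' Tips map to their species; an internal node maps to the species-tree MRCA
#' of its children's images.  The map is monotone: the image of a parent is
#' an ancestor of (or equal to) the image of each child.
#'
#' @param gtree rooted gene tree.
#' @param stree species tree.
#' @param delimiter gene-label delimiter.
#' @return integer vector over gene-tree node ids (tips then internals)
#'   giving the species-tree node id each gene node maps to.
#' @export
lca_map <- function(gtree, stree, delimiter = "|") {
  stopifnot(inherits(gtree, "phylo"), inherits(stree, "phylo"))
  sp <- species_of_gene(gtree$tip.label, delimiter)
  sp_id <- match(sp, stree$tip.label)
  if (anyNA(sp_id))
    stop("gene tip species absent from species tree: ",
         paste(unique(sp[is.na(sp_id)]), collapse = ", "), call. = FALSE)
  mrca2 <- .mrca_fun(stree)
  ntip <- length(gtree$tip.label)
  map <- integer(ntip + gtree$Nnode)
  map[seq_len(ntip)] <- sp_id
  e <- ape::reorder.phylo(gtree, "postorder")$edge
  for (i in seq_len(nrow(e))) {
    par <- e[i, 1L]; child <- e[i, 2L]
    map[par] <- if (map[par] == 0L) map[child] else mrca2(map[par], map[child])
  }
  map
}

#' Classify a duplication by subclade retention pattern
#'
#' Given the species sets of the two gene subclades (`s1`, `s2`) and the
#' species node the duplication maps to, a duplication is of type
#' \describe{
#'   \item{`"ABAB"`}{both subclades contain species from both descendant
#'     lineages A and B of the mapped node -- the pattern expected when both
#'     copies of an ancestral duplication were retained across the split;}
#'   \item{`"tip"`}{the mapped node is a terminal species (within-species
#'     paralogs);}
#'   \item{`"partial"`}{otherwise.}
#' }
#'
#' @param s1,s2 character vectors: species in each gene subclade.
#' @param species_node mapped species-tree node id.
#' @param stree species tree.
#' @return `"ABAB"`, `"partial"` or `"tip"`.
#' @export
classify_duplication <- function(s1, s2, species_node, stree) {
  ntip <- length(stree$tip.label)
  if (species_node <= ntip) return("tip")
  kids <- .children_list(stree)[[species_node]]
  tipsets <- .clade_tip_ids(stree)
  a <- stree$tip.label[tipsets[[kids[1L]]]]
  b <- stree$tip.label[unlist(tipsets[kids[-1L]])]
  if (any(s1 %in% a) && any(s1 %in% b) && any(s2 %in% a) && any(s2 %in% b))
    "ABAB" else "partial"
}

#' Detect duplication events in one gene tree
#'
#' @param gtree rooted gene tree.
#' @param stree species tree.
#' @param min_support retain a duplication only if the minimum of its two
#'   child-branch supports is at least this value (0--100 scale; default 50).
#'   Tip children contribute support 100.
#' @param delimiter gene-label delimiter.
#' @param missing_support `"fail"` (default) drops duplications whose child
#'   support is absent; `"pass"` treats absent support as 100.
#' @return data frame with one row per retained duplication: `gene_node`,
#'   `species_node`, `support`, `type` (`"ABAB"`, `"partial"`, `"tip"`).
#'   Polytomous gene nodes are never duplications themselves (soft
#'   polytomies); duplications below them are detected normally.
#' @export
detect_duplications <- function(gtree, stree, min_support = 50,
                                delimiter = "|",
                                missing_support = c("fail", "pass")) {
  missing_support <- match.arg(missing_support)
  empty <- data.frame(gene_node = integer(0), species_node = integer(0),
                      support = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (!inherits(gtree, "phylo")) return(empty)   # degenerate (single-copy) family
  if (length(gtree$tip.label) < 2L) return(empty)
  map <- lca_map(gtree, stree, delimiter)
  sup <- gene_supports(gtree)
  ntip <- length(gtree$tip.label)
  kids <- .children_list(gtree)
  # species set of each gene clade
  tipsets <- .clade_tip_ids(gtree)
  sp <- species_of_gene(gtree$tip.label, delimiter)

  child_support <- function(v) {
    if (v <= ntip) return(100)
    s <- sup[v - ntip]
    if (is.na(s) && missing_support == "pass") 100 else s
  }

  out <- empty
  for (v in (ntip + 1L):(ntip + gtree$Nnode)) {
    ch <- kids[[v]]
    if (length(ch) != 2L) next                    # soft polytomy: never a dup
    if (map[ch[1L]] != map[v] && map[ch[2L]] != map[v]) next
    s <- min(child_support(ch[1L]), child_support(ch[2L]))
    if (is.na(s) || s < min_support) next
    s1 <- unique(sp[tipsets[[ch[1L]]]])
    s2 <- unique(sp[tipsets[[ch[2L]]]])
    out <- rbind(out, data.frame(
      gene_node = v, species_node = map[v], support = s,
      type = classify_duplication(s1, s2, map[v], stree),
      stringsAsFactors = FALSE))
  }
  out
}

# species present in a gene tree (handles degenerate single-copy families
# stored as a bare tip label)
.gene_tree_species <- function(gt, delimiter = "|") {
  if (inherits(gt, "phylo")) unique(species_of_gene(gt$tip.label, delimiter))
  else if (is.character(gt)) unique(species_of_gene(gt, delimiter))
  else character(0)
}

#' Per-species-node duplication statistics
#'
#' Tallies retained duplication events over a collection of gene trees.  For
#' each species-tree node: the total event count (`gd_count`), the ABAB
#' count and fraction, the number of *relevant* gene trees, and the GD ratio
#' = (number of relevant trees with at least one retained duplication at the
#' node) / (number of relevant trees).
#'
#' A gene tree is *relevant* for an internal node when it contains at least
#' one species from each descendant lineage of the node (so a duplication
#' there is in principle observable); for a terminal node, when it contains
#' at least two gene copies of that species.  A node with zero relevant
#' trees has `gd_ratio = NA` (undefined, not 0).
#'
#' Multiple duplications of one tree at the same node all count toward
#' `gd_count` but the tree counts once in the ratio numerator.
#'
#' @param events data frame of events as returned by
#'   [detect_duplications()], plus a `tree` column identifying the source
#'   gene tree (as produced by [map_duplications()]).
#' @param gtrees named list of the gene trees the events came from.
#' @param stree species tree.
#' @param delimiter gene-label delimiter.
#' @return data frame, one row per species-tree node: `node`, `label`,
#'   `is_tip`, `gd_count`, `abab_count`, `abab_fraction`,
#'   `relevant_tree_count`, `trees_with_gd`, `gd_ratio`.
#' @export
summarize_by_node <- function(events, gtrees, stree, delimiter = "|") {
  ntip <- length(stree$tip.label)
  nn <- ntip + stree$Nnode
  kids <- .children_list(stree)
  tipsets <- .clade_tip_ids(stree)
  gd_count <- abab <- relevant <- with_gd <- integer(nn)

  if (nrow(events)) {
    tab <- table(factor(events$species_node, levels = seq_len(nn)))
    gd_count <- as.integer(tab)
    tab_ab <- table(factor(events$species_node[events$type == "ABAB"],
                           levels = seq_len(nn)))
    abab <- as.integer(tab_ab)
    # one tree counts once per node in the ratio numerator
    uniq <- unique(events[, c("tree", "species_node")])
    tab_tr <- table(factor(uniq$species_node, levels = seq_len(nn)))
    with_gd <- as.integer(tab_tr)
  }

  # relevance: species occupancy per tree, copies per species for tip nodes
  for (gt in gtrees) {
    if (inherits(gt, "phylo")) {
      sp_all <- species_of_gene(gt$tip.label, delimiter)
    } else if (is.character(gt)) {
      sp_all <- species_of_gene(gt, delimiter)
    } else next
    present <- match(unique(sp_all), stree$tip.label)
    copies <- table(sp_all)
    for (v in seq_len(nn)) {
      if (v <= ntip) {
        lab <- stree$tip.label[v]
        if (!is.na(copies[lab]) && copies[lab] >= 2L)
          relevant[v] <- relevant[v] + 1L
      } else {
        ch <- kids[[v]]
        ok <- TRUE
        for (c1 in ch) {
          if (!any(present %in% tipsets[[c1]])) { ok <- FALSE; break }
        }
        if (ok) relevant[v] <- relevant[v] + 1L
      }
    }
  }

  labels <- c(stree$tip.label,
              if (!is.null(stree$node.label)) stree$node.label
              else rep("", stree$Nnode))
  data.frame(
    node = seq_len(nn),
    label = labels,
    is_tip = seq_len(nn) <= ntip,
    gd_count = gd_count,
    abab_count = abab,
    abab_fraction = ifelse(gd_count > 0, abab / gd_count, NA_real_),
    relevant_tree_count = relevant,
    trees_with_gd = with_gd,
    gd_ratio = ifelse(relevant > 0, with_gd / relevant, NA_real_),
    stringsAsFactors = FALSE)
}

#' Map duplications from a set of gene trees onto the species tree
#'
#' The central fitting step: optionally roots each gene tree on an outgroup,
#' LCA-maps it, detects support-filtered duplication events, classifies them
#' (ABAB/partial/tip) and tallies per-node statistics.
#'
#' @param gene_trees a gene tree or (possibly named) list of gene trees.
#'   Entries that are bare character labels are treated as degenerate
#'   single-copy families (they contribute to relevant-tree counts only).
#' @param species_tree the reference species tree.
#' @param min_support,delimiter,missing_support see [detect_duplications()].
#' @param outgroups optional character vector of outgroup species; when
#'   given, each gene tree is rooted with [root_by_outgroup()] and trees
#'   lacking outgroup tips are skipped (recorded in `$skipped`).
#' @return an object of class `gd_map` with components `events` (one row per
#'   retained duplication; columns `tree`, `gene_node`, `species_node`,
#'   `support`, `type`), `node_stats` (see [summarize_by_node()]),
#'   `n_trees`, `skipped`, and the call parameters.
#' @seealso [detect_cgd()] for burst calling on the result.
#' @export
map_duplications <- function(gene_trees, species_tree, min_support = 50,
                             delimiter = "|", outgroups = NULL,
                             missing_support = c("fail", "pass")) {
  missing_support <- match.arg(missing_support)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (is.null(names(gene_trees)) || any(!nzchar(names(gene_trees))))
    names(gene_trees) <- sprintf("gt%04d", seq_along(gene_trees))

  skipped <- character(0)
  if (!is.null(outgroups)) {
    for (id in names(gene_trees)) {
      gt <- gene_trees[[id]]
      if (!inherits(gt, "phylo")) next
      rooted <- tryCatch(root_by_outgroup(gt, outgroups, delimiter),
                         phylogd_unrootable = function(e) NULL)
      if (is.null(rooted)) skipped <- c(skipped, id)
      else gene_trees[[id]] <- rooted
    }
    if (length(skipped)) {
      message(length(skipped), " gene tree(s) lacked outgroup tips; skipped")
      gene_trees <- gene_trees[setdiff(names(gene_trees), skipped)]
    }
  }

  ev_list <- lapply(names(gene_trees), function(id) {
    ev <- detect_duplications(gene_trees[[id]], species_tree, min_support,
                              delimiter, missing_support)
    if (nrow(ev)) cbind(tree = id, ev, stringsAsFactors = FALSE)
    else cbind(tree = character(0), ev)
  })
  events <- do.call(rbind, ev_list)
  if (is.null(events) || nrow(events) == 0L)
    events <- data.frame(tree = character(0), gene_node = integer(0),
                         species_node = integer(0), support = numeric(0),
                         type = character(0), stringsAsFactors = FALSE)
  rownames(events) <- NULL

  structure(list(
    events = events,
    node_stats = summarize_by_node(events, gene_trees, species_tree,
                                   delimiter),
    species_tree = species_tree,
    n_trees = length(gene_trees),
    skipped = skipped,
    min_support = min_support,
    delimiter = delimiter
  ), class = "gd_map")
}

#' @export
print.gd_map <- function(x, ...) {
  cat("Gene-duplication map:", nrow(x$events), "retained duplication(s)",
      "from", x$n_trees, "gene tree(s)\n")
  cat("  support filter: min", x$min_support, "\n")
  if (length(x$skipped))
    cat("  skipped (unrootable):", length(x$skipped), "tree(s)\n")
  top <- x$node_stats[x$node_stats$gd_count > 0, ]
  if (nrow(top)) {
    top <- top[order(-top$gd_count), ][seq_len(min(5L, nrow(top))), ]
    cat("  top nodes by GD count:\n")
    print(top[, c("node", "label", "gd_count", "gd_ratio", "abab_fraction")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.gd_map <- function(object, ...) {
  ns <- object$node_stats
  structure(list(
    n_trees = object$n_trees,
    n_events = nrow(object$events),
    n_abab = sum(object$events$type == "ABAB"),
    n_tip = sum(object$events$type == "tip"),
    node_stats = ns[order(-ns$gd_count), ]
  ), class = "summary.gd_map")
}

#' @export
print.summary.gd_map <- function(x, ...) {
  cat("Duplications:", x$n_events, "retained (", x$n_abab, "ABAB,",
      x$n_tip, "within-species ) from", x$n_trees, "trees\n")
  cat("Per-node statistics (sorted by GD count):\n")
  print(x$node_stats, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.gd_map <- function(x, ...) {
  ns <- x$node_stats[!x$node_stats$is_tip, ]
  graphics::barplot(ns$gd_count,
                    names.arg = ifelse(nzchar(ns$label), ns$label, ns$node),
                    las = 2, ylab = "retained duplications",
                    xlab = "species-tree node", ...)
  invisible(x)
}
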