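# Tree and feature-table input/output.
#
# Species and gene trees are ape "phylo" objects carrying an extra S3 class
# ("species_tree" / "gene_tree") so that methods and validators can tell the
# two roles apart.  Node ids follow ape's numbering: tips 1..Ntip in input
# order, internal nodes Ntip+1..Ntip+Nnode with the root at Ntip+1.  For a
# given newick string this numbering is deterministic, which is all the
# downstream bookkeeping needs.

#' Parse a newick string into a species or gene tree
#'
#' @param text a newick string (terminated by `;`).
#' @param kind `"species"` for a reference species tree (tip labels must be
#'   unique species identifiers) or `"gene"` for a gene family tree (tip
#'   labels of the form `species<delimiter>gene`, internal node labels read
#'   as bootstrap support on the 0--100 scale).
#'
#' @return an object of class `c("species_tree", "phylo")` or
#'   `c("gene_tree", "phylo")`.
#'
#' @details Support values are taken from internal node labels, the common
#'   newick dialect for bootstrap proportions.  Empty labels become `NA`
#'   support; how missing support is treated is decided by consumers (see
#'   [detect_duplications()]).  Branch lengths are carried through untouched;
#'   their units (time for species trees, substitutions/site for gene trees)
#'   are interpreted by consumers, not here.
#'
#' @examples
#' stree <- parse_newick("((A:1,B:1):1,C:2);", "species")
#' gtree <- parse_newick("((A|g1,B|g1)95,(A|g2,B|g2)80)100;", "gene")
#' gene_supports(gtree)
#' @export
parse_newick <- function(text, kind = c("species", "gene")) {
  kind <- match.arg(kind)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(phy))
    stop("newick parse error: no tree found in input", call. = FALSE)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("expected exactly one tree, got ", length(phy), call. = FALSE)
    phy <- phy[[1L]]
  }
  if (kind == "species") as_species_tree(phy) else as_gene_tree(phy)
}

#' @rdname parse_newick
#' @param phy an ape `phylo` object.
#' @export
as_species_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate species tip labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!ape::is.rooted(phy))
    stop("species tree must be rooted", call. = FALSE)
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("species tree has negative branch lengths", call. = FALSE)
  class(phy) <- c("species_tree", "phylo")
  phy
}

#' @rdname parse_newick
#' @export
as_gene_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  sup <- .parse_supports(phy$node.label, phy$Nnode)
  bad <- !is.na(sup) & (sup < 0 | sup > 100)
  if (any(bad))
    stop("gene tree support values outside [0, 100]: ",
         paste(sup[bad], collapse = ", "), call. = FALSE)
  class(phy) <- c("gene_tree", "phylo")
  phy
}

.parse_supports <- function(labels, nnode) {
  if (is.null(labels)) return(rep(NA_real_, nnode))
  sup <- suppressWarnings(as.numeric(labels))
  sup[!nzchar(labels %||% "")] <- NA_real_
  sup
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Internal-node support values of a gene tree
#'
#' @param gtree a gene tree from [parse_newick()].
#' @return numeric vector of length `Nnode` (order: ape node numbering,
#'   root first), `NA` where no support was present.
#' @export
gene_supports <- function(gtree) {
  stopifnot(inherits(gtree, "phylo"))
  .parse_supports(gtree$node.label, gtree$Nnode)
}

#' Read a tree from a newick file
#'
#' @inheritParams parse_newick
#' @param path path to a newick file (first tree is used).
#' @export
read_tree <- function(path, kind = c("species", "gene")) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = "\n"), kind)
}

#' Write a tree to newick
#'
#' Round-trips topology, tip labels, internal-node labels (supports) and
#' branch lengths to printed precision.
#'
#' @param tree a `phylo` object.
#' @param path file path, or `NULL` to return the newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Species identifier encoded in a gene tip label
#'
#' Gene tip labels are `species<delimiter>gene`; the species id is the
#' substring before the FIRST delimiter occurrence, so gene ids may
#' themselves contain the delimiter.
#'
#' @param label character vector of gene tip labels.
#' @param delimiter single string separating species from gene id
#'   (default `"|"`).
#' @return character vector of species ids.
#' @examples
#' species_of_gene("Triticum_aestivum|TraesCS5A01G1")  # "Triticum_aestivum"
#' species_of_gene("A|g1|iso2")                        # "A"
#' @export
species_of_gene <- function(label, delimiter = "|") {
  stopifnot(is.character(label), nchar(delimiter) >= 1L)
  pos <- regexpr(delimiter, label, fixed = TRUE)
  if (any(pos < 0L))
    stop("gene label(s) lack the delimiter \"", delimiter, "\": ",
         paste(label[pos < 0L], collapse = ", "), call. = FALSE)
  substr(label, 1L, pos - 1L)
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels (one tip returns the tip's
#'   own node id).
#' @return integer node id (ape numbering).
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 1L)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  idx <- unique(idx)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Resolve a node reference (label or comma-separated tip set) to a node id
#'
#' @param tree a `phylo` object.
#' @param ref a node label, a tip label, or a comma-separated tip set whose
#'   MRCA is taken.
#' @return integer node id.
#' @export
resolve_node <- function(tree, ref) {
  stopifnot(is.character(ref), length(ref) == 1L)
  ref <- trimws(ref)
  ntip <- length(tree$tip.label)
  if (!grepl(",", ref, fixed = TRUE)) {
    hit <- match(ref, tree$tip.label)
    if (!is.na(hit)) return(hit)
    if (!is.null(tree$node.label)) {
      hit <- match(ref, tree$node.label)
      if (!is.na(hit)) return(ntip + hit)
    }
    stop("cannot resolve node reference \"", ref, "\"", call. = FALSE)
  }
  tips <- trimws(strsplit(ref, ",", fixed = TRUE)[[1L]])
  tips <- tips[nzchar(tips)]
  mrca_node(tree, tips)
}

#' Construct a validated feature node set
#'
#' A feature node set names a class of events anchored to species-tree nodes
#' (duplication bursts, diversification-rate upshifts, trait transitions)
#' and lists the nodes carrying that feature.
#'
#' @param tree the species tree the nodes live on.
#' @param nodes integer node ids (duplicates removed, sorted).
#' @param name feature class name, e.g. `"rate_shifts"`.
#' @return object of class `feature_set`.
#' @export
feature_set <- function(tree, nodes, name = "feature") {
  stopifnot(inherits(tree, "phylo"))
  nodes <- as.integer(nodes)
  nmax <- length(tree$tip.label) + tree$Nnode
  if (length(nodes) && (any(nodes < 1L) || any(nodes > nmax)))
    stop("node id(s) outside the tree: ",
         paste(nodes[nodes < 1L | nodes > nmax], collapse = ", "),
         call. = FALSE)
  structure(list(name = name, nodes = sort(unique(nodes))),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature node set \"", x$name, "\": ", length(x$nodes), " node(s)\n",
      sep = "")
  if (length(x$nodes)) cat("  ids:", paste(x$nodes, collapse = " "), "\n")
  invisible(x)
}

#' Read a feature node table
#'
#' One row per feature node: either a node/tip label, or a comma-separated
#' tip set resolved to its MRCA.  Empty files give an empty set.  Lines
#' starting with `#` are comments.
#'
#' @param path path to the table.
#' @param tree the species tree.
#' @param name feature class name (default: file base name).
#' @return a [feature_set()].
#' @export
read_feature_nodes <- function(path, tree, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  nodes <- integer(0)
  for (i in keep) {
    node <- tryCatch(resolve_node(tree, lines[[i]]), error = function(e)
      stop("row ", i, " of ", path, ": ", conditionMessage(e), call. = FALSE))
    nodes <- c(nodes, node)
  }
  feature_set(tree, nodes, name)
}

#' Write a feature node table (one resolvable row per node)
#'
#' Internal nodes are written as the comma-separated tip set of their clade,
#' tips as their label, so the file round-trips through
#' [read_feature_nodes()] on the same tree.
#'
#' @param fs a [feature_set()].
#' @param tree the species tree.
#' @param path output path.
#' @export
write_feature_nodes <- function(fs, tree, path) {
  rows <- vapply(fs$nodes, function(v) {
    paste(clade_tips(tree, v), collapse = ",")
  }, character(1))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Tip labels of the clade below a node
#'
#' @param tree a `phylo` object.
#' @param node integer node id.
#' @return character vector of tip labels.
#' @export
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- .clade_tip_ids(tree)[[node]]
  tree$tip.label[kids]
}

# --- internal topology helpers (shared across modules) ----------------------

# children of every node, as a list indexed by node id
.children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  out <- vector("list", n)
  e <- tree$edge
  split_idx <- split(e[, 2L], e[, 1L])
  for (nm in names(split_idx)) out[[as.integer(nm)]] <- split_idx[[nm]]
  out
}

# parent of every node (0 for the root)
.parent_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# depth (edges from root) of every node
.depth_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- .parent_vec(tree)
  d <- rep(NA_integer_, n)
  root <- length(tree$tip.label) + 1L
  d[root] <- 0L
  # edges in preorder: reorder guarantees parents before children
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(e))) d[e[i, 2L]] <- d[e[i, 1L]] + 1L
  d
}

# tip ids (integer) under every node, as a list indexed by node id
.clade_tip_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- i
  e <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(e))) {
    out[[e[i, 1L]]] <- c(out[[e[i, 1L]]], out[[e[i, 2L]]])
  }
  out
}

# fast pairwise MRCA on a rooted tree via parent/depth walking
.mrca_fun <- function(tree) {
  par <- .parent_vec(tree)
  dep <- .depth_vec(tree)
  function(a, b) {
    while (a != b) {
      if (dep[a] >= dep[b]) a <- par[a] else b <- par[b]
    }
    a
  }
}

# node-to-node distances in edge counts (topological)
.edge_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(tree$edge))
  ape::dist.nodes(t2)
}
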