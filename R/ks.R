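# Paralog-pair collection and Ks-distribution peak detection.

#' Collect within-species paralog pairs descending from duplication events
#'
#' For each retained duplication event and the requested species, takes one
#' gene from each of the event's two subclades.  When several genes of the
#' species occur in a subclade, the pair with the longest aligned overlap
#' (codon columns valid in both sequences) is chosen; ties, or absent
#' sequences, fall back to the lexicographically smallest gene ids, making
#' the choice deterministic.
#'
#' @param events event table from [map_duplications()] (`$events`) or
#'   [detect_duplications()] with a `tree` column.
#' @param gene_trees named list of gene trees the events refer to.
#' @param species species id whose paralog pairs are wanted.
#' @param sequences optional named character vector of aligned CDS used for
#'   the overlap criterion.
#' @param delimiter gene-label delimiter.
#' @return data frame, one row per event with the species present in both
#'   subclades: `pair_id`, `tree`, `gene_node`, `species_node`, `gene_a`,
#'   `gene_b` (sorted so `gene_a < gene_b`).
#' @export
collect_paralog_pairs <- function(events, gene_trees, species,
                                  sequences = NULL, delimiter = "|") {
  if (inherits(events, "gd_map")) events <- events$events
  stopifnot(is.data.frame(events))
  out <- list()
  for (i in seq_len(nrow(events))) {
    gt <- gene_trees[[events$tree[i]]]
    if (!inherits(gt, "phylo")) next
    kids <- .children_list(gt)[[events$gene_node[i]]]
    if (length(kids) != 2L) next
    tipsets <- .clade_tip_ids(gt)
    pick <- function(k) {
      labs <- gt$tip.label[tipsets[[k]]]
      sort(labs[species_of_gene(labs, delimiter) == species])
    }
    g1 <- pick(kids[1L]); g2 <- pick(kids[2L])
    if (length(g1) == 0L || length(g2) == 0L) next
    best <- c(g1[1L], g2[1L])
    if (!is.null(sequences) && (length(g1) > 1L || length(g2) > 1L)) {
      best_ov <- -1
      for (a in g1) for (b in g2) {
        if (!(a %in% names(sequences)) || !(b %in% names(sequences))) next
        ov <- .aligned_overlap(sequences[[a]], sequences[[b]])
        if (ov > best_ov) { best_ov <- ov; best <- c(a, b) }
      }
    }
    pr <- sort(best)
    out[[length(out) + 1L]] <- data.frame(
      pair_id = paste(pr[1L], pr[2L], sep = "__"),
      tree = events$tree[i], gene_node = events$gene_node[i],
      species_node = events$species_node[i],
      gene_a = pr[1L], gene_b = pr[2L], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(pair_id = character(0), tree = character(0),
                      gene_node = integer(0), species_node = integer(0),
                      gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# codon columns usable in both sequences of a putative pair
.aligned_overlap <- function(a, b) {
  ca <- .split_codons(a); cb <- .split_codons(b)
  n <- min(length(ca), length(cb))
  sum(grepl("^[ACGT]{3}$", toupper(ca[seq_len(n)])) &
        grepl("^[ACGT]{3}$", toupper(cb[seq_len(n)])))
}

#' Locate the mode of a Ks distribution
#'
#' Gaussian kernel density over the Ks values clipped to `range`, evaluated
#' on a 1,000-point grid; the peak is the grid argmax.  Values outside the
#' range (including saturated pairs, reported as `NA` Ks) are excluded and
#' tallied.
#'
#' @param ks_values numeric vector of Ks estimates (may contain `NA`).
#' @param range search interval, default `c(0.01, 2)`.
#' @param bandwidth `"silverman"` (default; Silverman's rule of thumb on the
#'   clipped values) or a positive number.
#' @return object of class `ks_peak`: `location`, `density`, `bandwidth`,
#'   `range`, `n_used`, `n_excluded`, and the density grid (`grid_x`,
#'   `grid_y`).
#' @export
ks_peak <- function(ks_values, range = c(0.01, 2), bandwidth = "silverman") {
  stopifnot(length(range) == 2L, range[1L] < range[2L])
  x <- ks_values[is.finite(ks_values)]
  x <- x[x >= range[1L] & x <= range[2L]]
  n_excl <- length(ks_values) - length(x)
  if (length(x) < 20L)
    stop("insufficient data: ", length(x),
         " finite Ks values in range (need >= 20)", call. = FALSE)
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(x)
  else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  d <- stats::density(x, bw = bw, from = range[1L], to = range[2L], n = 1000L)
  i <- which.max(d$y)
  structure(list(location = d$x[i], density = d$y[i], bandwidth = bw,
                 range = range, n_used = length(x), n_excluded = n_excl,
                 grid_x = d$x, grid_y = d$y),
            class = "ks_peak")
}

#' @export
print.ks_peak <- function(x, ...) {
  cat(sprintf(
    "Ks peak at %.4f (density %.3f, bandwidth %.4f) from %d values in [%g, %g]\n",
    x$location, x$density, x$bandwidth, x$n_used, x$range[1L], x$range[2L]))
  if (x$n_excluded)
    cat("  excluded (out of range / saturated / NA):", x$n_excluded, "\n")
  invisible(x)
}

#' @export
plot.ks_peak <- function(x, ...) {
  graphics::plot(x$grid_x, x$grid_y, type = "l", xlab = "Ks",
                 ylab = "density", ...)
  graphics::abline(v = x$location, lty = 2)
  invisible(x)
}
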