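# Clustered gene-duplication (CGD) burst calling.
#
# A node is called a burst -- a candidate whole-genome duplication -- when it
# simultaneously shows (1) a large absolute number of retained duplications,
# (2) a large fraction of relevant gene trees duplicated there, and (3) a
# large fraction of ABAB-type duplications.  All comparisons are inclusive
# (>=).  The stock thresholds (600 duplications, 6% of relevant trees, 30%
# ABAB) are calibrated to surveys on the order of 45,000 gene trees; use
# scale_thresholds() to adapt the count threshold to smaller collections.

#' Scale the duplication-count threshold to a different survey size
#'
#' `min_gd * n_trees_actual / n_trees_reference`, rounded half-up with a
#' floor of 1.
#'
#' @param min_gd count threshold at the reference survey size.
#' @param n_trees_reference survey size the threshold was calibrated on
#'   (default 45722 gene trees).
#' @param n_trees_actual size of the survey at hand.
#' @return scaled integer threshold.
#' @examples
#' scale_thresholds(600, n_trees_actual = 4572)  # 60
#' @export
scale_thresholds <- function(min_gd, n_trees_reference = 45722,
                             n_trees_actual) {
  if (min_gd <= 0 || n_trees_reference <= 0 || n_trees_actual <= 0)
    stop("all counts must be positive", call. = FALSE)
  max(1L, as.integer(floor(min_gd * n_trees_actual / n_trees_reference + 0.5)))
}

#' Call clustered gene-duplication bursts
#'
#' @param stats per-node statistics from [summarize_by_node()], or a
#'   `gd_map` object (its `$node_stats` is used).
#' @param min_gd minimum retained duplication count (default 600).
#' @param min_ratio minimum GD ratio, i.e. fraction of relevant gene trees
#'   with a duplication at the node (default 0.06).
#' @param min_abab minimum ABAB fraction among the node's duplications
#'   (default 0.30).
#' @param scale_to if not `NULL`, rescale `min_gd` for a survey of this many
#'   gene trees via [scale_thresholds()].
#' @return object of class `cgd_calls`: a data frame with one row per
#'   species-tree node, sorted by `gd_count` descending, with the statistics,
#'   a `passed` flag and a `reason` column (`""` when passed;
#'   `"undefined_ratio"` marks nodes with no relevant trees, which never
#'   pass).  Thresholds used are attached as attributes.
#' @export
detect_cgd <- function(stats, min_gd = 600, min_ratio = 0.06,
                       min_abab = 0.30, scale_to = NULL) {
  if (inherits(stats, "gd_map")) stats <- stats$node_stats
  stopifnot(is.data.frame(stats),
            all(c("node", "gd_count", "gd_ratio", "abab_fraction",
                  "relevant_tree_count") %in% names(stats)))
  if (!is.null(scale_to))
    min_gd <- scale_thresholds(min_gd, n_trees_actual = scale_to)

  undef <- is.na(stats$gd_ratio)
  pass_count <- stats$gd_count >= min_gd
  pass_ratio <- !undef & stats$gd_ratio >= min_ratio
  pass_abab  <- !is.na(stats$abab_fraction) & stats$abab_fraction >= min_abab
  passed <- pass_count & pass_ratio & pass_abab

  reason <- character(nrow(stats))
  reason[!passed & undef] <- "undefined_ratio"
  reason[!passed & !undef] <- apply(
    cbind(count = !pass_count[!undef & !passed],
          ratio = !pass_ratio[!undef & !passed],
          abab = !pass_abab[!undef & !passed]), 1L,
    function(f) paste(names(f)[f], collapse = "+"))

  out <- cbind(stats, passed = passed, reason = reason)
  out <- out[order(-out$gd_count, out$node), ]
  rownames(out) <- NULL
  structure(out, class = c("cgd_calls", "data.frame"),
            min_gd = min_gd, min_ratio = min_ratio, min_abab = min_abab)
}

#' @export
print.cgd_calls <- function(x, ...) {
  cat("CGD burst calls (thresholds: count >=", attr(x, "min_gd"),
      ", ratio >=", attr(x, "min_ratio"),
      ", ABAB >=", attr(x, "min_abab"), ")\n")
  hits <- x[x$passed, , drop = FALSE]
  cat(nrow(hits), "node(s) passed\n")
  cols <- c("node", "label", "gd_count", "gd_ratio", "abab_fraction",
            "passed", "reason")
  print.data.frame(utils::head(x[, cols], 12L), row.names = FALSE, digits = 3)
  if (nrow(x) > 12L) cat("  ...", nrow(x) - 12L, "more node(s)\n")
  invisible(x)
}
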