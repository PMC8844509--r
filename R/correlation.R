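# Randomized-placement coincidence tests between node-feature sets on the
# species tree (duplication bursts vs. diversification-rate upshifts vs.
# trait transitions).
#
# The null keeps one feature set fixed and redraws the other uniformly
# without replacement from the eligible nodes (internal nodes, root
# included), preserving its cardinality.  P-values use the add-one
# estimator P = (1 + #{null >= observed}) / (1 + n_rand), so the smallest
# attainable value is 1/(n_rand + 1) and 0 is never returned.

#' Eligible nodes for feature randomization
#'
#' Internal nodes of the species tree, root included; features are anchored
#' to MRCAs, so tips are excluded by default.
#'
#' @param tree species tree.
#' @return integer vector of node ids.
#' @export
eligible_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  (ntip + 1L):(ntip + tree$Nnode)
}

#' Count coincidences between two feature node sets
#'
#' With `radius = 0`, the size of the intersection.  With `radius = r > 0`,
#' the number of nodes of `a` having some node of `b` within `r` edges on
#' the tree (each `a` node counted once).
#'
#' @param a,b [feature_set()] objects or integer node-id vectors.
#' @param tree species tree.
#' @param radius nonnegative integer match radius in edges (default 0,
#'   exact node identity).
#' @return integer coincidence count.
#' @export
coincidence_count <- function(a, b, tree, radius = 0L) {
  if (inherits(a, "feature_set")) a <- a$nodes
  if (inherits(b, "feature_set")) b <- b$nodes
  if (radius < 0) stop("radius must be nonnegative", call. = FALSE)
  if (radius == 0) return(length(intersect(a, b)))
  if (length(a) == 0L || length(b) == 0L) return(0L)
  D <- .edge_dist(tree)
  sum(vapply(a, function(v) any(D[v, b] <= radius), logical(1)))
}

#' Randomly place a feature set on the tree
#'
#' Uniform sample of `k` nodes without replacement from the eligible nodes.
#'
#' @param tree species tree.
#' @param k number of nodes to draw.
#' @param eligible integer vector of candidate node ids (default
#'   [eligible_nodes()]).
#' @param seed optional integer seed.
#' @param name feature name for the result.
#' @return a [feature_set()].
#' @export
randomize_feature_nodes <- function(tree, k, eligible = NULL, seed = NULL,
                                    name = "random") {
  if (is.null(eligible)) eligible <- eligible_nodes(tree)
  if (k > length(eligible))
    stop("k = ", k, " exceeds the ", length(eligible), " eligible nodes",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  feature_set(tree, sample(eligible, k), name)
}

#' Randomized-placement coincidence test
#'
#' Tests whether two feature node sets coincide on the species tree more
#' often than expected if one of them were placed at random.  Per repeat,
#' `n_rand` random placements of the designated set (same cardinality,
#' uniform over eligible nodes) are drawn, coincidences with the fixed set
#' counted, and `P = (1 + #[null >= observed]) / (1 + n_rand)`.  The
#' repeats (default 100) give a P-value distribution summarizing Monte
#' Carlo spread.
#'
#' @param a,b [feature_set()] objects (or integer node-id vectors).
#' @param tree species tree.
#' @param scheme which set is randomized under the null: `"randomize-B"`
#'   (default) or `"randomize-A"`.
#' @param n_rand random placements per repeat (default 1000).
#' @param n_repeats number of repeats (default 100).
#' @param radius match radius in edges (see [coincidence_count()]).
#' @param seed master seed; per-repeat seeds are derived from it so repeats
#'   are independent and the whole run is reproducible.
#' @param eligible candidate nodes for randomization (default
#'   [eligible_nodes()]).
#' @return object of class `gd_coincidence`: observed count, `p_values`
#'   (one per repeat), quantile summary, and the test configuration.
#' @export
permutation_test <- function(a, b, tree,
                             scheme = c("randomize-B", "randomize-A"),
                             n_rand = 1000L, n_repeats = 100L, radius = 0L,
                             seed = NULL, eligible = NULL) {
  scheme <- match.arg(scheme)
  name_a <- if (inherits(a, "feature_set")) a$name else "A"
  name_b <- if (inherits(b, "feature_set")) b$name else "B"
  if (inherits(a, "feature_set")) a <- a$nodes
  if (inherits(b, "feature_set")) b <- b$nodes
  if (length(a) == 0L || length(b) == 0L)
    stop("degenerate feature set: both sets must be nonempty", call. = FALSE)
  if (is.null(eligible)) eligible <- eligible_nodes(tree)
  obs <- coincidence_count(a, b, tree, radius)

  rand_set <- if (scheme == "randomize-B") b else a
  fixed_set <- if (scheme == "randomize-B") a else b
  k <- length(rand_set)
  if (k > length(eligible))
    stop("randomized set larger than the eligible node pool", call. = FALSE)
  n_elig <- length(eligible)

  # indicator machinery: at radius 0 a draw's count is how many of its nodes
  # lie in (or, randomizing B with radius>0 reversed roles, near) the fixed
  # set; the asymmetric radius>0 case scans the distance matrix per draw.
  D <- if (radius > 0) .edge_dist(tree) else NULL
  if (radius == 0) {
    ind <- as.integer(eligible %in% fixed_set)
    draw_count <- function() sum(ind[sample.int(n_elig, k)])
  } else if (scheme == "randomize-A") {
    # count = # randomized A-nodes within radius of fixed B
    ind <- vapply(eligible, function(v) any(D[v, fixed_set] <= radius),
                  logical(1))
    draw_count <- function() sum(ind[sample.int(n_elig, k)])
  } else {
    # count = # fixed A-nodes within radius of randomized B
    Dsub <- D[fixed_set, eligible, drop = FALSE]
    draw_count <- function() {
      idx <- sample.int(n_elig, k)
      sum(apply(Dsub[, idx, drop = FALSE] <= radius, 1L, any))
    }
  }

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_repeats)
  p_values <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(rep_seeds[r])
    null_ge <- 0L
    for (i in seq_len(n_rand)) if (draw_count() >= obs) null_ge <- null_ge + 1L
    p_values[r] <- (1 + null_ge) / (1 + n_rand)
  }

  structure(list(
    feature_a = name_a, feature_b = name_b,
    observed = obs, scheme = scheme, radius = radius,
    n_rand = n_rand, n_repeats = n_repeats, seed = seed,
    k_a = length(a), k_b = length(b),
    p_values = p_values,
    quantiles = stats::quantile(p_values, c(0, 0.25, 0.5, 0.75, 1))
  ), class = "gd_coincidence")
}

#' @export
print.gd_coincidence <- function(x, ...) {
  cat("Coincidence test:", x$feature_a, "(k=", x$k_a, ") vs",
      x$feature_b, "(k=", x$k_b, "),", x$scheme,
      ", radius", x$radius, "\n")
  cat("  observed coincidences:", x$observed, "\n")
  cat(sprintf("  P over %d repeat(s) of %d randomizations: median %.4g [%.4g, %.4g]\n",
              x$n_repeats, x$n_rand, stats::median(x$p_values),
              min(x$p_values), max(x$p_values)))
  invisible(x)
}

#' @export
summary.gd_coincidence <- function(object, ...) {
  data.frame(feature_a = object$feature_a, feature_b = object$feature_b,
             scheme = object$scheme, radius = object$radius,
             observed = object$observed,
             p_median = stats::median(object$p_values),
             p_q25 = unname(object$quantiles[2L]),
             p_q75 = unname(object$quantiles[4L]),
             p_min = min(object$p_values), p_max = max(object$p_values),
             stringsAsFactors = FALSE)
}

#' @export
plot.gd_coincidence <- function(x, ...) {
  graphics::boxplot(x$p_values, ylab = "P value", ylim = c(0, max(1, x$p_values)),
                    main = paste(x$feature_a, "vs", x$feature_b,
                                 paste0("(", x$scheme, ")")), ...)
  graphics::abline(h = 0.05, lty = 2, col = "grey40")
  invisible(x)
}

#' Run all pairwise coincidence tests under both null schemes
#'
#' @param features named list of [feature_set()] objects (at least two),
#'   e.g. `list(gd_bursts = ..., rate_shifts = ..., trait_transitions = ...)`.
#' @inheritParams permutation_test
#' @return object of class `gd_coincidence_set`: list of
#'   [permutation_test()] results (one per unordered pair per scheme, i.e.
#'   `choose(m, 2) * 2` rows for `m` sets) and a `$summary` data frame.
#' @export
run_pairwise_tests <- function(features, tree, n_rand = 1000L,
                               n_repeats = 100L, radius = 0L, seed = NULL) {
  stopifnot(is.list(features))
  if (length(features) < 2L)
    stop("need at least two feature sets", call. = FALSE)
  if (is.null(names(features)))
    names(features) <- paste0("F", seq_along(features))
  if (!is.null(seed)) set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max,
                           choose(length(features), 2L) * 2L)
  results <- list(); s <- 0L
  nms <- names(features)
  for (i in seq_len(length(features) - 1L)) for (j in (i + 1L):length(features)) {
    for (scheme in c("randomize-B", "randomize-A")) {
      s <- s + 1L
      res <- permutation_test(features[[i]], features[[j]], tree,
                              scheme = scheme, n_rand = n_rand,
                              n_repeats = n_repeats, radius = radius,
                              seed = pair_seeds[s])
      results[[paste(nms[i], nms[j], scheme, sep = ".")]] <- res
    }
  }
  structure(list(results = results,
                 summary = do.call(rbind, lapply(results, summary))),
            class = "gd_coincidence_set")
}

#' @export
print.gd_coincidence_set <- function(x, ...) {
  cat("Pairwise coincidence tests (", length(x$results), " test(s) )\n",
      sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.gd_coincidence_set <- function(x, ...) {
  pv <- lapply(x$results, `[[`, "p_values")
  graphics::boxplot(pv, las = 2, ylab = "P value", ...)
  graphics::abline(h = 0.05, lty = 2, col = "grey40")
  invisible(x)
}
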