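# Nei-Gojobori (1986) synonymous/nonsynonymous divergence for aligned,
# in-frame CDS pairs, with Jukes-Cantor correction.
#
# Site counting: at each codon position the synonymous fraction is the
# number of the 3 possible nucleotide changes that preserve the amino acid,
# divided by 3; changes creating a stop codon count as nonsynonymous, so
# S + N = 3 x (codons used) exactly.  Differences: for codons differing at
# d positions, all d! single-step pathways are enumerated, pathways passing
# through a stop codon are discarded, and synonymous/nonsynonymous step
# counts are averaged over the remaining pathways (over all pathways, with
# stop-involving steps counted nonsynonymous, in the rare case every pathway
# is blocked).

.ng86 <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.ng86$codons)) return(.ng86)
  bases <- c("T", "C", "A", "G")
  # standard genetic code, codons in TCAG order with third position fastest
  aa64 <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  names(aa64) <- codons
  stopifnot(aa64[["ATG"]] == "M", aa64[["TGG"]] == "W", aa64[["TAA"]] == "*")

  is_stop <- aa64 == "*"
  # per-codon synonymous site count
  syn_sites <- setNames(numeric(64L), codons)
  syn_changes <- setNames(vector("list", 64L), codons)  # synonymous 1-nt neighbours
  for (cd in codons) {
    if (is_stop[[cd]]) { syn_sites[[cd]] <- NA_real_; next }
    s <- 0; nb <- character(0)
    cv <- strsplit(cd, "")[[1L]]
    for (pos in 1:3) for (b in bases) {
      if (b == cv[pos]) next
      alt <- cv; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (!is_stop[[alt]] && aa64[[alt]] == aa64[[cd]]) {
        s <- s + 1
        nb <- c(nb, alt)
      }
    }
    syn_sites[[cd]] <- s / 3
    syn_changes[[cd]] <- nb
  }

  .ng86$bases <- bases
  .ng86$codons <- codons
  .ng86$aa <- aa64
  .ng86$is_stop <- is_stop
  .ng86$syn_sites <- syn_sites
  .ng86$syn_changes <- syn_changes
  .ng86$pair_cache <- new.env(parent = emptyenv())
  .ng86
}

# averaged (synonymous, nonsynonymous) difference counts for one codon pair
.pair_sd_nd <- function(c1, c2) {
  tb <- .codon_tables()
  if (c1 == c2) return(c(0, 0))
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- tb$pair_cache[[key]]
  if (!is.null(hit)) return(hit)

  v1 <- strsplit(c1, "")[[1L]]
  v2 <- strsplit(c2, "")[[1L]]
  pos <- which(v1 != v2)
  perms <- .permutations(pos)
  walk <- function(order, allow_stop) {
    cur <- v1; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- v2[p]
      ccur <- paste(cur, collapse = ""); cnxt <- paste(nxt, collapse = "")
      if (tb$is_stop[[cnxt]] && !allow_stop) return(NULL)
      if (!tb$is_stop[[ccur]] && !tb$is_stop[[cnxt]] &&
          tb$aa[[ccur]] == tb$aa[[cnxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(perms, walk, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    res <- lapply(perms, walk, allow_stop = TRUE)
  out <- Reduce(`+`, res) / length(res)
  tb$pair_cache[[key]] <- out
  out
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

.split_codons <- function(s) {
  s <- toupper(gsub("U", "T", s))
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori Ks/Ka for one aligned in-frame CDS pair
#'
#' @param cds_a,cds_b aligned coding sequences (equal length, multiple of
#'   3; `U` accepted for `T`).  Codon columns containing a gap (`-`), an
#'   ambiguous base, or a stop codon in either sequence are excluded
#'   pairwise.
#' @return one-row data frame of class `ks_result`: `codons_used`,
#'   `codons_excluded`, `S`, `N` (synonymous/nonsynonymous sites, averaged
#'   over the two sequences), `Sd`, `Nd` (pathway-averaged differences),
#'   `ps`, `pn` (proportions), `Ks`, `Ka` (Jukes-Cantor-corrected rates per
#'   site; `NA` with the corresponding `saturated_*` flag set when the
#'   proportion reaches 3/4).
#' @examples
#' r <- ng86_pair(paste0("ATGGCT", strrep("AAA", 20)),
#'                paste0("ATGGCC", strrep("AAA", 20)))
#' r$Ks > 0 && r$Ka == 0
#' @export
ng86_pair <- function(cds_a, cds_b) {
  tb <- .codon_tables()
  ca <- .split_codons(cds_a)
  cb <- .split_codons(cds_b)
  if (length(ca) != length(cb))
    stop("aligned sequences differ in length (", nchar(cds_a), " vs ",
         nchar(cds_b), ")", call. = FALSE)
  okpat <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ok <- okpat
  ok[okpat] <- !(tb$is_stop[ca[okpat]] | tb$is_stop[cb[okpat]])
  ca <- ca[ok]; cb <- cb[ok]
  ncod <- length(ca)
  if (ncod == 0L)
    stop("no usable codon columns in the pair", call. = FALSE)

  S <- (sum(tb$syn_sites[ca]) + sum(tb$syn_sites[cb])) / 2
  N <- 3 * ncod - S
  sd_nd <- c(0, 0)
  diff <- which(ca != cb)
  for (i in diff) sd_nd <- sd_nd + .pair_sd_nd(ca[i], cb[i])
  ps <- if (S > 0) sd_nd[1L] / S else 0
  pn <- if (N > 0) sd_nd[2L] / N else 0
  sat_s <- ps >= 0.75
  sat_n <- pn >= 0.75
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  out <- data.frame(
    codons_used = ncod, codons_excluded = sum(!ok),
    S = S, N = N, Sd = sd_nd[1L], Nd = sd_nd[2L], ps = ps, pn = pn,
    Ks = if (sat_s) NA_real_ else jc(ps),
    Ka = if (sat_n) NA_real_ else jc(pn),
    saturated_ks = sat_s, saturated_kn = sat_n,
    stringsAsFactors = FALSE)
  class(out) <- c("ks_result", "data.frame")
  out
}

#' Ks/Ka for a table of sequence pairs
#'
#' @param pairs data frame with columns `gene_a`, `gene_b` (and optionally
#'   `pair_id`), e.g. from [collect_paralog_pairs()].
#' @param sequences named character vector of aligned CDS, indexed by gene
#'   id.
#' @return data frame: pair identifiers plus all [ng86_pair()] columns.
#'   Pairs with a missing sequence are dropped with a message.
#' @export
ks_for_pairs <- function(pairs, sequences) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  if (is.null(pairs$pair_id))
    pairs$pair_id <- paste(pairs$gene_a, pairs$gene_b, sep = "__")
  have <- pairs$gene_a %in% names(sequences) &
    pairs$gene_b %in% names(sequences)
  if (any(!have))
    message(sum(!have), " pair(s) dropped: sequence missing")
  pairs <- pairs[have, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i)
    ng86_pair(sequences[[pairs$gene_a[i]]], sequences[[pairs$gene_b[i]]]))
  out <- cbind(pairs, do.call(rbind, lapply(res, as.data.frame)))
  rownames(out) <- NULL
  out
}
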