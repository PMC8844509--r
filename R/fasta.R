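# Minimal plain-text FASTA support for aligned CDS (no wrapping tricks, no
# compression): enough for moving simulated alignments through the CLI and
# tests deterministically.

#' Read sequences from a FASTA file
#'
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of sequences (names: header up to the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(setNames(character(0), character(0)))
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  setNames(unname(seqs), id)
}

#' Write sequences to a FASTA file
#'
#' Sequences are written unwrapped, one per record, LF line endings.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width optional line width for wrapping (default: no wrapping).
#' @export
write_fasta <- function(seqs, path, width = NULL) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    body <- if (is.null(width)) s
    else substring(s, seq(1L, nchar(s), width),
                   pmin(seq(width, nchar(s) + width - 1L, width), nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), body), con, useBytes = TRUE)
  }
  invisible(path)
}
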