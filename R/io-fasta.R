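#' Read sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Assemble a read table from FASTA plus an optional quality table
#'
#' @param path FASTA of reads.
#' @param quality_table Optional path to a TSV with columns `read_id` and
#'   `quality` (predicted accuracy fraction) and optionally `n_passes`.
#' @return A read tibble: `read_id`, `sequence`, `quality` (`NA` when no
#'   instrument-reported value exists) and `n_passes`.
#' @export
reads_from_fasta <- function(path, quality_table = NULL) {
  seqs <- read_fasta(path)
  out <- tibble(read_id = names(seqs), sequence = unname(seqs),
                quality = NA_real_, n_passes = 1L)
  if (!is.null(quality_table)) {
    q <- utils::read.delim(quality_table, stringsAsFactors = FALSE)
    if (!all(c("read_id", "quality") %in% names(q))) {
      abort("quality table needs columns read_id and quality")
    }
    out$quality <- q$quality[match(out$read_id, q$read_id)]
    if ("n_passes" %in% names(q)) {
      np <- q$n_passes[match(out$read_id, q$read_id)]
      out$n_passes <- as.integer(ifelse(is.na(np), 1L, np))
    }
  }
  out
}
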