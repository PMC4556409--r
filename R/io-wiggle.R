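#' Read per-base coverage from a wiggle file
#'
#' Supports the `fixedStep` and `variableStep` dialects (with `span`).
#' Positions absent from the file have no row; contiguous runs of covered
#' positions form tracks, so a gap in the input splits a track.
#'
#' @param path Path to a wiggle file.
#' @return A coverage tibble with one row per covered base: `scaffold`,
#'   `pos` (0-based) and `depth` (non-negative, possibly fractional), sorted
#'   by scaffold then position.
#' @export
read_wiggle <- function(path) {
  empty <- tibble(scaffold = character(), pos = integer(), depth = double())
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^[0-9.+-]", raw))) return(empty)
  gr <- rtracklayer::import(path, format = "wig")
  if (is(gr, "GRangesList")) gr <- unlist(gr, use.names = FALSE)
  if (!length(gr)) return(empty)
  s0 <- BiocGenerics::start(gr) - 1L
  w <- BiocGenerics::width(gr)
  out <- tibble(
    scaffold = rep(as.character(GenomicRanges::seqnames(gr)), w),
    pos = as.integer(sequence(w, from = s0)),
    depth = rep(gr$score, w)
  ) |>
    arrange(.data$scaffold, .data$pos)
  if (any(out$depth < 0)) {
    abort("wiggle parse error: negative coverage value")
  }
  out
}

#' Write per-base coverage to a wiggle file
#'
#' Each contiguous run of covered positions is emitted as one
#' `fixedStep step=1 span=1` block (1-based start). Fractional depths are
#' written with full precision so that a read/write cycle is lossless.
#'
#' @param coverage Coverage tibble as from [read_wiggle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(coverage, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("track type=wiggle_0", con)
  if (nrow(coverage)) {
    if (any(coverage$depth < 0)) abort("coverage depth must be >= 0")
    cov <- coverage |> arrange(.data$scaffold, .data$pos)
    brk <- c(TRUE, cov$scaffold[-1L] != cov$scaffold[-nrow(cov)] |
                     cov$pos[-1L] != cov$pos[-nrow(cov)] + 1L)
    run <- cumsum(brk)
    vals <- ifelse(cov$depth == round(cov$depth),
                   sprintf("%.0f", cov$depth),
                   sprintf("%.17g", cov$depth))
    for (r in split(seq_len(nrow(cov)), run)) {
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1 span=1",
                         cov$scaffold[r[1L]], cov$pos[r[1L]] + 1L), con)
      writeLines(vals[r], con)
    }
  }
  invisible(path)
}

# Split a coverage tibble into contiguous tracks; returns a list-free tibble
# with a `track` id column (per scaffold-contiguous run).
coverage_tracks <- function(coverage) {
  if (!nrow(coverage)) return(mutate(coverage, track = integer()))
  cov <- coverage |> arrange(.data$scaffold, .data$pos)
  brk <- c(TRUE, cov$scaffold[-1L] != cov$scaffold[-nrow(cov)] |
                   cov$pos[-1L] != cov$pos[-nrow(cov)] + 1L)
  mutate(cov, track = cumsum(brk))
}
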