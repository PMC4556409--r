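#' Interval conventions
#'
#' All genomic coordinates inside the package are 0-based, half-open
#' `[start, end)` on an ascending genomic axis; minus-strand features store
#' their intervals in ascending genomic order and biological (transcript)
#' order is derived where needed. GFF emission converts to 1-based inclusive
#' coordinates at the single I/O boundary.
#'
#' @name interval-conventions
#' @keywords internal
NULL

# Assert 0 <= start < end and non-empty scaffolds on an interval tibble.
check_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)) ||
      any(df$start < 0) || any(df$start >= df$end)) {
    abort(paste0("invalid ", what, ": need 0 <= start < end"))
  }
  if (any(is.na(df$scaffold)) || any(df$scaffold == "")) {
    abort(paste0("invalid ", what, ": empty scaffold name"))
  }
  invisible(df)
}

# Union of intervals (start/end vectors, 0-based half-open) on one scaffold.
# Returns a two-column matrix of merged intervals sorted by start.
merge_runs <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (length(start) == 0L) return(cbind(start = integer(), end = integer()))
  # a new run begins where start exceeds the running max end (touching splits)
  cm <- cummax(end)
  brk <- c(TRUE, start[-1L] > cm[-length(cm)])
  grp <- cumsum(brk)
  cbind(start = tapply(start, grp, min),
        end = tapply(end, grp, max))
}

# Number of bases in [s1,e1) covered by the union of intervals (s2, e2).
bases_covered <- function(s1, e1, s2, e2) {
  if (length(s2) == 0L) return(0L)
  m <- merge_runs(s2, e2)
  sum(pmax(0L, pmin(e1, m[, "end"]) - pmax(s1, m[, "start"])))
}

# TRUE iff [s1,e1) lies entirely within the union of intervals (s2, e2).
fully_covered <- function(s1, e1, s2, e2) {
  bases_covered(s1, e1, s2, e2) == (e1 - s1)
}

# Total overlap in bases between two interval sets on the same scaffold.
overlap_bases <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  m1 <- merge_runs(s1, e1); m2 <- merge_runs(s2, e2)
  tot <- 0
  for (i in seq_len(nrow(m1))) {
    tot <- tot + sum(pmax(0, pmin(m1[i, "end"], m2[, "end"]) -
                            pmax(m1[i, "start"], m2[, "start"])))
  }
  tot
}

# Connected components of span overlap. `df` needs start/end columns; rows
# already restricted to one scaffold (+ strand if desired). Returns an
# integer component id per row of `df` (in input order).
overlap_components <- function(start, end) {
  n <- length(start)
  if (n == 0L) return(integer())
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  cm <- cummax(e)
  brk <- c(TRUE, s[-1L] >= cm[-n])  # touching intervals do not overlap
  comp_sorted <- cumsum(brk)
  comp <- integer(n)
  comp[o] <- comp_sorted
  comp
}

#' Intron chains of gene models or spliced alignments
#'
#' The intron chain of a multi-block feature is the ordered list of
#' `(donor, acceptor)` junction coordinates between consecutive blocks;
#' equality of intron chains defines "same splice structure". A feature with
#' `k` blocks has `k - 1` introns.
#'
#' @param x A gene-model tibble (one row per exon, see [read_gff3_genes()])
#'   or spliced-alignment tibble (one row per block, see
#'   [read_gff3_alignments()]).
#' @param id_col Column identifying a feature; defaults to `"transcript_id"`
#'   when present, else `"read_id"`.
#'
#' @return A tibble with one row per intron: the feature id, `scaffold`,
#'   `strand`, `intron_rank`, `start` (donor, 0-based) and `end` (acceptor,
#'   exclusive).
#' @examples
#' g <- tibble::tibble(gene_id = "g1", transcript_id = "g1.t1",
#'   scaffold = "s1", strand = "+", start = c(100L, 300L),
#'   end = c(200L, 400L), exon_rank = 1:2,
#'   cds_start = 120L, cds_end = 380L)
#' intron_chains(g)
#' @export
intron_chains <- function(x, id_col = NULL) {
  if (is.null(id_col)) {
    id_col <- if ("transcript_id" %in% names(x)) "transcript_id" else "read_id"
  }
  x |>
    arrange(.data[[id_col]], .data$start) |>
    group_by(id = .data[[id_col]], .data$scaffold, .data$strand) |>
    reframe(donor = head(.data$end, -1L),
            acceptor = tail(.data$start, -1L)) |>
    rename(start = "donor", end = "acceptor") |>
    group_by(.data$id) |>
    mutate(intron_rank = row_number()) |>
    ungroup() |>
    rename_with(~id_col, "id")
}

# Compact chain key per feature: "scaffold:strand:d1-a1;d2-a2;...".
# Featureless of introns -> "scaffold:strand:" (intron-free chain).
chain_keys <- function(x, id_col = NULL) {
  if (is.null(id_col)) {
    id_col <- if ("transcript_id" %in% names(x)) "transcript_id" else "read_id"
  }
  x |>
    arrange(.data[[id_col]], .data$start) |>
    group_by(id = .data[[id_col]]) |>
    summarise(
      scaffold = .data$scaffold[1L],
      strand = .data$strand[1L],
      chain = paste(head(.data$end, -1L), tail(.data$start, -1L),
                    sep = "-", collapse = ";"),
      span_start = min(.data$start),
      span_end = max(.data$end),
      n_blocks = n(),
      .groups = "drop"
    ) |>
    mutate(chain_key = paste(.data$scaffold, .data$strand, .data$chain,
                             sep = ":")) |>
    rename_with(~id_col, "id")
}

# Split a span by an intron chain (";"-joined "d-a" pairs) into exon blocks.
# Returns a tibble(start, end). Chain junctions must lie inside the span.
chain_to_exons <- function(span_start, span_end, chain) {
  if (is.na(chain) || chain == "") {
    return(tibble(start = span_start, end = span_end))
  }
  parts <- str_split(str_split(chain, ";")[[1]], "-")
  d <- as.integer(map_chr(parts, 1L))
  a <- as.integer(map_chr(parts, 2L))
  tibble(start = c(span_start, a), end = c(d, span_end))
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
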