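#' Length/quality prefilter for raw subreads
#'
#' Discards subreads shorter than `cfg$min_subread_len` (50 bases) and reads
#' whose instrument-predicted accuracy falls below `cfg$min_read_quality`
#' (0.75, i.e. an expected error rate above 25\%). Both comparisons are
#' strict removals, so a 50-base read at quality 0.75 is kept. Reads without
#' a reported quality pass the quality filter: the cutoff applies to
#' instrument-reported values only.
#'
#' @param reads Read tibble with columns `read_id`, `sequence` and
#'   optionally `quality` (fraction in `[0, 1]` or `NA`).
#' @param cfg A [pipeline_config()].
#' @return The retained rows of `reads`.
#' @export
prefilter_reads <- function(reads, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  q <- if ("quality" %in% names(reads)) reads$quality else NA_real_
  keep <- nchar(reads$sequence) >= cfg$min_subread_len &
    (is.na(q) | q >= cfg$min_read_quality)
  reads[keep, , drop = FALSE]
}

#' Locate a cDNA synthesis primer near a read end
#'
#' Performs a semi-global alignment (primer global, read local; unit
#' mismatch/indel costs) of the primer against the terminal
#' `cfg$primer_window` bases of each sequence. For the 3' end the reverse
#' complement of the primer is searched at the read's tail. A match is
#' reported when `identity` reaches `cfg$primer_identity`; identity is
#' edit-distance based, `1 - edits / primer length` (so two mismatches in a
#' 24-mer give 22/24 = 0.917), which keeps gap-scattered chance matches in
#' random sequence from passing the cutoff.
#'
#' @param sequences Character vector of read sequences (sense orientation of
#'   the search, i.e. already oriented by the caller).
#' @param primer Primer sequence (as synthesized, 5'->3'); at least
#'   `cfg$min_primer_len` bases.
#' @param end `"5prime"` to search the read start, `"3prime"` to search the
#'   reverse complement of the primer at the read end.
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per sequence: `start`, `end` (0-based
#'   half-open match coordinates in the read; `NA` when below the identity
#'   cutoff), `identity` and `matched`.
#' @export
detect_primer <- function(sequences, primer, end = c("5prime", "3prime"),
                          cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  end <- match.arg(end)
  if (nchar(primer) < cfg$min_primer_len) {
    abort(paste0("primer shorter than ", cfg$min_primer_len, " bases"))
  }
  n <- length(sequences)
  out <- tibble(start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                identity = rep(0, n), matched = rep(FALSE, n))
  if (n == 0L) return(out)
  query <- if (end == "3prime") revcomp(primer) else primer
  len <- nchar(sequences)
  w <- pmin(len, cfg$primer_window)
  off <- if (end == "5prime") rep(0L, n) else len - w
  windows <- substr(sequences, off + 1L, off + w)
  ok <- nchar(windows) > 0L
  if (!any(ok)) return(out)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(windows[ok]),
    subject = Biostrings::DNAString(query),
    type = "local-global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 1)
  # identity = 1 - edits/len; with unit costs score = len - 2*edits
  idn <- pmax(0, pmin(1, (BiocGenerics::score(al) + nchar(primer)) /
                        (2 * nchar(primer))))
  ms <- off[ok] + BiocGenerics::start(Biostrings::pattern(al)) - 1L
  me <- off[ok] + BiocGenerics::end(Biostrings::pattern(al))
  hit <- idn >= cfg$primer_identity
  out$identity[ok] <- idn
  out$matched[ok] <- hit
  out$start[ok] <- ifelse(hit, as.integer(ms), NA_integer_)
  out$end[ok] <- ifelse(hit, as.integer(me), NA_integer_)
  out
}

#' Detect a terminal poly(A) tail
#'
#' Scans for the longest window ending at `end_pos` (the located 3' primer
#' start, or the read end) whose A-fraction is at least
#' `cfg$polya_min_frac` (0.90) and whose length is at least
#' `cfg$polya_min_len` (20 bases). The longest qualifying window wins, so a
#' single interior non-A base inside an otherwise pure tail is tolerated;
#' leading non-A bases are then stripped from the winning window (a tail
#' starts on an A), so the reported tail never eats into a transcript whose
#' 3' end is not A-rich.
#'
#' @param sequences Character vector of sense-strand read sequences.
#' @param end_pos Integer vector (recycled): 0-based exclusive position where
#'   the tail must end; defaults to the read length.
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per sequence: `polya_start` (0-based, `NA`
#'   when no qualifying window exists) and `polya_length` (0 when absent).
#' @export
detect_polya <- function(sequences, end_pos = NULL,
                         cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  n <- length(sequences)
  if (is.null(end_pos)) end_pos <- nchar(sequences)
  end_pos <- rep_len(as.integer(end_pos), n)
  res <- map2(sequences, end_pos, function(s, e) {
    e <- min(e, nchar(s))
    if (e < cfg$polya_min_len) return(c(NA_integer_, 0L))
    isA <- as.integer(strsplit(substr(s, 1L, e), "", fixed = TRUE)[[1]] == "A")
    csA <- c(0L, cumsum(isA))
    i <- 0:(e - cfg$polya_min_len)  # candidate window starts (0-based)
    frac <- (csA[e + 1L] - csA[i + 1L]) / (e - i)
    hit <- which(frac >= cfg$polya_min_frac)
    if (!length(hit)) return(c(NA_integer_, 0L))
    st <- i[hit[1L]]
    while (st < e && isA[st + 1L] == 0L) st <- st + 1L  # tails start on an A
    if (e - st < cfg$polya_min_len) return(c(NA_integer_, 0L))
    c(st, e - st)
  })
  tibble(polya_start = map_int(res, 1L), polya_length = map_int(res, 2L))
}

#' Classify reads as full-insert cDNA and trim them
#'
#' A read is *full-insert* -- taken to represent an entire transcript -- when
#' both the 5' and 3' cDNA synthesis primers and a poly(A) tail are present.
#' Primers and the tail are trimmed off; the retained insert is reported on
#' the sense strand. If the reverse complement of the read carries the
#' stronger primer evidence, the read is treated as antisense and flipped
#' before trimming. Reads whose located primer regions overlap are flagged
#' `conflicted` and never called full-insert.
#'
#' @param reads Read tibble (`read_id`, `sequence`, optional `quality`).
#' @param primer5,primer3 The 5' and 3' synthesis primer sequences.
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per read: `read_id`, `orientation`
#'   (`"sense"`/`"antisense"`), `has_5prime`, `has_3prime`, `polya_length`,
#'   `insert` (trimmed, sense strand), `conflicted` and `full_insert`.
#' @examples
#' reads <- tibble::tibble(read_id = "r1",
#'   sequence = paste0("ACGGTAGCATTGCAGGACTTCAGT",
#'                     strrep("TGCA", 30), "CCGT", strrep("A", 25),
#'                     "ACCAGTCGCAACTTAGGCATCGTA"))
#' classify_reads(reads, "ACGGTAGCATTGCAGGACTTCAGT",
#'                "TACGATGCCTAAGTTGCGACTGGT")
#' @export
classify_reads <- function(reads, primer5, primer3,
                           cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  n <- nrow(reads)
  if (n == 0L) {
    return(tibble(read_id = character(), orientation = character(),
                  has_5prime = logical(), has_3prime = logical(),
                  polya_length = integer(), insert = character(),
                  conflicted = logical(), full_insert = logical()))
  }
  sense <- reads$sequence
  anti <- revcomp(sense)
  m5s <- detect_primer(sense, primer5, "5prime", cfg)
  m3s <- detect_primer(sense, primer3, "3prime", cfg)
  m5a <- detect_primer(anti, primer5, "5prime", cfg)
  m3a <- detect_primer(anti, primer3, "3prime", cfg)
  score_s <- m5s$matched + m3s$matched
  score_a <- m5a$matched + m3a$matched
  id_s <- m5s$identity + m3s$identity
  id_a <- m5a$identity + m3a$identity
  use_anti <- score_a > score_s | (score_a == score_s & id_a > id_s)
  seq_o <- ifelse(use_anti, anti, sense)
  m5 <- m5s; m3 <- m3s
  m5[use_anti, ] <- m5a[use_anti, ]
  m3[use_anti, ] <- m3a[use_anti, ]
  len <- nchar(seq_o)
  p3_start <- ifelse(m3$matched, m3$start, len)
  pa <- detect_polya(seq_o, end_pos = p3_start, cfg = cfg)
  insert_start <- ifelse(m5$matched, m5$end, 0L)
  insert_end <- ifelse(is.na(pa$polya_start), p3_start, pa$polya_start)
  conflicted <- (m5$matched & m3$matched & m5$end > m3$start) |
    (m5$matched & insert_start > insert_end)
  insert_end <- pmax(insert_end, insert_start)
  tibble(
    read_id = reads$read_id,
    orientation = ifelse(use_anti, "antisense", "sense"),
    has_5prime = m5$matched,
    has_3prime = m3$matched,
    polya_length = pa$polya_length,
    insert = substr(seq_o, insert_start + 1L, insert_end),
    conflicted = conflicted,
    full_insert = m5$matched & m3$matched &
      pa$polya_length >= cfg$polya_min_len & !conflicted
  )
}
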