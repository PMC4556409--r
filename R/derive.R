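#' Cluster spliced alignments by intron chain
#'
#' Two alignments fall into the same cluster when they carry an identical
#' intron chain (same scaffold and strand) and their genomic spans overlap;
#' clusters are the connected components of span overlap within each chain.
#' Loci are the connected components of span overlap across *all*
#' same-strand alignments, so a locus can host several clusters (isoforms).
#' Opposite strands never merge.
#'
#' @param alignments Spliced-alignment tibble (typically pre-filtered with
#'   [filter_full_length_alignments()]).
#' @return A cluster tibble, one row per isoform cluster: `cluster_id`,
#'   `locus_id`, `scaffold`, `strand`, `chain` (";"-joined `donor-acceptor`
#'   pairs, `""` for intron-free), `n_reads`, `span_start`, `span_end`, and
#'   list-columns `read_ids`, `starts`, `ends` with the member reads and
#'   their span coordinates.
#' @export
cluster_by_intron_chain <- function(alignments) {
  empty <- tibble(cluster_id = character(), locus_id = character(),
                  scaffold = character(), strand = character(),
                  chain = character(), n_reads = integer(),
                  span_start = integer(), span_end = integer(),
                  read_ids = list(), starts = list(), ends = list())
  if (nrow(alignments) == 0L) return(empty)
  keys <- chain_keys(alignments, "read_id")
  keys <- keys |>
    group_by(.data$scaffold, .data$strand) |>
    mutate(locus = overlap_components(.data$span_start, .data$span_end)) |>
    group_by(.data$scaffold, .data$strand, .data$chain) |>
    mutate(comp = overlap_components(.data$span_start, .data$span_end)) |>
    ungroup()
  clusters <- keys |>
    group_by(.data$scaffold, .data$strand, .data$chain, .data$comp) |>
    summarise(locus = .data$locus[1L],
              n_reads = n(),
              read_ids = list(.data$read_id),
              starts = list(.data$span_start),
              ends = list(.data$span_end),
              span_start = min(.data$span_start),
              span_end = max(.data$span_end),
              .groups = "drop") |>
    arrange(.data$scaffold, .data$span_start, .data$strand, .data$chain)
  clusters |>
    mutate(cluster_id = sprintf("cl%05d", row_number())) |>
    group_by(.data$scaffold, .data$strand, .data$locus) |>
    mutate(locus_key = paste0(.data$scaffold[1L], .data$strand[1L],
                              min(.data$span_start))) |>
    ungroup() |>
    mutate(locus_id = sprintf("loc%05d",
                              match(.data$locus_key,
                                    unique(.data$locus_key)))) |>
    select("cluster_id", "locus_id", "scaffold", "strand", "chain",
           "n_reads", "span_start", "span_end", "read_ids", "starts",
           "ends")
}

#' Select the most abundant isoform per locus
#'
#' Within each locus the cluster with the most member reads wins; ties are
#' broken by longer genomic span, then leftmost start. A cluster qualifies
#' when it holds at least `cfg$min_isoform_reads` (2) reads, or -- in
#' hint-generation mode -- when it holds a single spliced read all of whose
#' junctions are independently confirmed by `intron_evidence`.
#'
#' @param clusters Cluster tibble from [cluster_by_intron_chain()].
#' @param cfg A [pipeline_config()].
#' @param intron_evidence Optional tibble of confirmed introns (`scaffold`,
#'   `start`, `end`), e.g. intron hints from short-read data.
#' @return The winning cluster rows, one per locus.
#' @export
select_isoforms <- function(clusters, cfg = pipeline_config(),
                            intron_evidence = NULL) {
  cfg <- as_config(cfg)
  if (nrow(clusters) == 0L) return(clusters)
  evid <- character()
  if (!is.null(intron_evidence) && nrow(intron_evidence)) {
    evid <- paste0(intron_evidence$scaffold, ":", intron_evidence$start,
                   "-", intron_evidence$end)
  }
  confirmed <- function(scaffold, chain) {
    if (chain == "") return(FALSE)  # intron-free singletons never qualify
    juncs <- paste0(scaffold, ":", str_split(chain, ";")[[1]])
    all(juncs %in% evid)
  }
  clusters |>
    mutate(eligible = .data$n_reads >= cfg$min_isoform_reads |
             (.data$n_reads >= 1L &
                map2_lgl(.data$scaffold, .data$chain, confirmed))) |>
    filter(.data$eligible) |>
    group_by(.data$locus_id) |>
    arrange(desc(.data$n_reads),
            desc(.data$span_end - .data$span_start),
            .data$span_start, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select(-"eligible") |>
    arrange(.data$scaffold, .data$span_start)
}

#' Derive transcript boundaries from cluster members
#'
#' The transcript start (stop) is the median of the member alignment start
#' (end) positions; even member counts use the lower median so that the
#' boundary is always an observed coordinate.
#'
#' @param clusters Cluster tibble (e.g. from [select_isoforms()]).
#' @return `clusters` with `start` and `end` columns added.
#' @export
derive_boundaries <- function(clusters) {
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  clusters |>
    mutate(start = map_int(.data$starts, ~as.integer(lower_median(.x))),
           end = map_int(.data$ends, ~as.integer(lower_median(.x))))
}

#' Longest open reading frame of a transcript sequence
#'
#' Scans the three forward frames of a sense-strand transcript for
#' `ATG`..stop ORFs and returns the longest one (ties: leftmost start). The
#' stop codon is part of the reported span but not of the protein.
#'
#' @param sequence A sense-strand DNA string.
#' @param min_codons Minimum protein length in codons (default 100);
#'   shorter ORFs are not reported.
#' @return A one-row tibble `start`, `end` (0-based half-open within the
#'   transcript), `protein`; zero rows when no qualifying ORF exists.
#' @examples
#' find_orf("ATGAAATAA", min_codons = 1)
#' @export
find_orf <- function(sequence, min_codons = 100L) {
  s <- toupper(sequence)
  n <- nchar(s)
  best <- NULL
  for (f in 0:2) {
    if (n - f < 6L) next
    idx <- seq.int(f, n - 3L, by = 3L)  # 0-based codon starts
    codons <- substring(s, idx + 1L, idx + 3L)
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(starts) || !length(stops)) next
    nxt <- findInterval(starts, stops) + 1L  # first stop after each start
    ok <- nxt <= length(stops)
    starts <- starts[ok]; nxt <- nxt[ok]
    if (!length(starts)) next
    aa_len <- stops[nxt] - starts
    # keep the longest ORF per stop (the first ATG of each stop's frame run)
    for (j in seq_along(starts)) {
      if (aa_len[j] < min_codons) next
      cand <- list(start = idx[starts[j]], end = idx[stops[nxt[j]]] + 3L,
                   aa = aa_len[j],
                   codons = codons[starts[j]:(stops[nxt[j]] - 1L)])
      if (is.null(best) || cand$aa > best$aa ||
          (cand$aa == best$aa && cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(tibble(start = integer(), end = integer(), protein = character()))
  }
  protein <- paste(Biostrings::GENETIC_CODE[best$codons], collapse = "")
  tibble(start = as.integer(best$start), end = as.integer(best$end),
         protein = protein)
}

#' Derive gene models from clustered full-insert alignments
#'
#' Full pipeline for annotation-free gene discovery: full-length filter,
#' intron-chain clustering, most-abundant-isoform selection, median
#' transcript boundaries, exon chain reconstruction, transcript extraction
#' from the genome and ORF calling. Candidates overlapping an `existing`
#' gene by one or more exon bases are dropped. Candidates without a
#' qualifying ORF are emitted without CDS and flagged (`attributes =
#' "orf=none"`).
#'
#' @param alignments Spliced-alignment tibble.
#' @param genome Named character vector of scaffold sequences (see
#'   [read_fasta()]).
#' @param existing Optional gene-model tibble of already accepted genes.
#' @param cfg A [pipeline_config()].
#' @param intron_evidence Optional confirmed-intron tibble passed to
#'   [select_isoforms()].
#' @return A gene-model tibble of the derived genes (one row per exon).
#' @export
derive_gene_models <- function(alignments, genome, existing = NULL,
                               cfg = pipeline_config(),
                               intron_evidence = NULL) {
  cfg <- as_config(cfg)
  empty <- tibble(gene_id = character(), transcript_id = character(),
                  scaffold = character(), strand = character(),
                  start = integer(), end = integer(), exon_rank = integer(),
                  cds_start = integer(), cds_end = integer(),
                  evidence_fraction = double(), attributes = character())
  if (nrow(alignments) == 0L) return(empty)
  picked <- alignments |>
    filter_full_length_alignments(cfg) |>
    cluster_by_intron_chain() |>
    select_isoforms(cfg, intron_evidence) |>
    derive_boundaries()
  if (nrow(picked) == 0L) return(empty)

  rows <- list()
  for (i in seq_len(nrow(picked))) {
    cl <- picked[i, ]
    ex <- chain_to_exons(cl$start, cl$end, cl$chain)
    if (any(ex$start >= ex$end)) next  # degenerate boundaries
    if (!is.null(existing) && nrow(existing)) {
      olap <- existing |>
        filter(.data$scaffold == cl$scaffold) |>
        summarise(b = overlap_bases(.data$start, .data$end, ex$start,
                                    ex$end)) |>
        pull("b")
    } else {
      olap <- 0
    }
    if (length(olap) && olap > 0) next
    txseq <- extract_transcript(genome, cl$scaffold, ex, cl$strand)
    orf <- find_orf(txseq, cfg$min_orf_codons)
    if (nrow(orf)) {
      g <- transcript_to_genome(c(orf$start, orf$end - 1L), ex, cl$strand)
      cds_start <- min(g); cds_end <- max(g) + 1L
      attr_str <- NA_character_
    } else {
      cds_start <- NA_integer_; cds_end <- NA_integer_
      attr_str <- "orf=none"
    }
    rows[[length(rows) + 1L]] <- tibble(
      scaffold = cl$scaffold, strand = cl$strand,
      start = as.integer(ex$start), end = as.integer(ex$end),
      exon_rank = seq_len(nrow(ex)),
      cds_start = cds_start, cds_end = cds_end,
      evidence_fraction = 1, attributes = attr_str,
      n_reads = cl$n_reads)
  }
  if (!length(rows)) return(empty)
  models <- bind_rows(rows, .id = "cand")
  ids <- models |>
    group_by(.data$cand) |>
    summarise(scaffold = .data$scaffold[1L],
              first_start = min(.data$start), .groups = "drop") |>
    arrange(.data$scaffold, .data$first_start) |>
    mutate(gene_id = sprintf("SMRT_%s_g%03d", .data$scaffold,
                             row_number())) |>
    select("cand", "gene_id")
  models |>
    left_join(ids, by = "cand") |>
    mutate(transcript_id = paste0(.data$gene_id, ".t1")) |>
    arrange(.data$scaffold, .data$gene_id, .data$start) |>
    select("gene_id", "transcript_id", "scaffold", "strand", "start",
           "end", "exon_rank", "cds_start", "cds_end",
           "evidence_fraction", "attributes")
}

# Spliced transcript sequence of an exon chain; minus strand is reverse
# complemented to sense orientation.
extract_transcript <- function(genome, scaffold, exons, strand) {
  seq <- genome[[scaffold]]
  if (is.null(seq)) abort(paste0("scaffold not in genome: ", scaffold))
  parts <- substring(seq, exons$start + 1L, exons$end)
  tx <- paste(parts, collapse = "")
  if (strand == "-") tx <- revcomp(tx)
  tx
}

# Map 0-based transcript positions to genomic positions through an exon
# chain (exons ascending genomic order).
transcript_to_genome <- function(pos, exons, strand) {
  lens <- exons$end - exons$start
  total <- sum(lens)
  if (any(pos < 0L | pos >= total)) abort("transcript position out of range")
  p <- if (strand == "-") total - 1L - pos else pos
  cum <- c(0L, cumsum(lens))
  i <- findInterval(p, cum, left.open = FALSE)  # exon index (1-based)
  i <- pmin(i, length(lens))
  exons$start[i] + (p - cum[i])
}
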