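#' Keep alignments that map a read at full length to a single locus
#'
#' A read maps at full length when it aligns with at least
#' `cfg$min_align_fraction` (90\%) of its length *and* misses at most
#' `cfg$max_missing_bases` (50) bases; the tolerance absorbs deletion errors
#' typical of single-molecule reads. Reads aligning to multiple genomic loci
#' (`n_hits > 1`) are removed.
#'
#' @param alignments Spliced-alignment tibble (see
#'   [read_gff3_alignments()]).
#' @param cfg A [pipeline_config()].
#' @return The retained alignment rows.
#' @export
filter_full_length_alignments <- function(alignments,
                                          cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (any(alignments$aligned_bases > alignments$read_length)) {
    abort("invalid alignment: aligned_bases exceeds read_length")
  }
  alignments |>
    filter(.data$n_hits == 1L,
           .data$aligned_bases / .data$read_length >=
             cfg$min_align_fraction,
           .data$read_length - .data$aligned_bases <= cfg$max_missing_bases)
}

#' Validate gene models with full-insert read alignments
#'
#' A gene model is `validated` when at least one alignment overlaps its
#' exons and *all* overlapping alignments confirm the same number and order
#' of exons with exactly the same intron boundaries, and at least one
#' overlapping alignment covers both the start and the stop codon (UTR
#' length may vary). It is `contradicted` when any overlapping alignment
#' carries a different intron chain, and `unsupported` when no alignment
#' overlaps its exons (or when chains agree but no alignment spans the CDS
#' ends). Models without a CDS cannot be validated and raise an error.
#'
#' @param genes Gene-model tibble; every transcript needs `cds_start`/
#'   `cds_end`.
#' @param alignments Spliced alignments, pre-filtered with
#'   [filter_full_length_alignments()].
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per transcript: `gene_id`,
#'   `transcript_id`, `status` (`validated`/`contradicted`/`unsupported`),
#'   `n_overlapping` and `n_confirming`.
#' @export
validate_gene_models <- function(genes, alignments,
                                 cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  tx <- chain_keys(genes, "transcript_id") |>
    left_join(distinct(genes, .data$transcript_id, .data$gene_id,
                       .data$cds_start, .data$cds_end),
              by = "transcript_id")
  if (any(is.na(tx$cds_start))) {
    abort(paste0("validation requires a CDS (start/stop codons); missing ",
                 "for: ",
                 paste(head(tx$transcript_id[is.na(tx$cds_start)], 3L),
                       collapse = ", ")))
  }
  aln_keys <- chain_keys(alignments, "read_id")
  status <- character(nrow(tx))
  n_over <- integer(nrow(tx))
  n_conf <- integer(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    ex <- genes |> filter(.data$transcript_id == t$transcript_id)
    cand <- aln_keys |> filter(.data$scaffold == t$scaffold,
                               .data$span_start < t$span_end,
                               .data$span_end > t$span_start)
    if (nrow(cand)) {
      blocks <- alignments |> filter(.data$read_id %in% cand$read_id)
      over_ids <- blocks |>
        inner_join(ex |> select(es = "start", ee = "end", "scaffold"),
                   by = "scaffold", relationship = "many-to-many") |>
        filter(.data$start < .data$ee, .data$end > .data$es) |>
        distinct(.data$read_id)
      cand <- cand |> semi_join(over_ids, by = "read_id")
    }
    n_over[i] <- nrow(cand)
    if (nrow(cand) == 0L) {
      status[i] <- "unsupported"
      next
    }
    model_chain <- paste(t$scaffold, t$strand, t$chain, sep = ":")
    same <- cand$chain_key == model_chain
    n_conf[i] <- sum(same)
    if (!all(same)) {
      status[i] <- "contradicted"
      next
    }
    # start/stop codon coverage: all three bases of each terminal codon
    # (projected through the exons -- a codon may straddle an intron)
    codon_pos <- terminal_cds_positions(ex, t$cds_start, t$cds_end)
    covered <- map_lgl(cand$read_id, function(rid) {
      b <- alignments |> filter(.data$read_id == rid)
      m <- merge_runs(b$start, b$end)
      all(map_lgl(codon_pos, function(p) {
        any(m[, "start"] <= p & p < m[, "end"])
      }))
    })
    status[i] <- if (any(covered)) "validated" else "unsupported"
  }
  tibble(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
         status = status, n_overlapping = n_over, n_confirming = n_conf)
}

# Genomic positions of the first and last three coding bases of a model,
# walking the CDS through its exons (codons may straddle introns).
terminal_cds_positions <- function(exons, cds_start, cds_end) {
  cx <- exons |>
    mutate(cs = pmax(.data$start, cds_start), ce = pmin(.data$end, cds_end)) |>
    filter(.data$cs < .data$ce) |>
    arrange(.data$cs)
  pos <- unlist(map2(cx$cs, cx$ce, ~.x:(.y - 1L)), use.names = FALSE)
  if (length(pos) < 3L) return(pos)
  c(head(pos, 3L), tail(pos, 3L))
}

#' Remove genes near scaffold borders
#'
#' Genes whose span intersects the first or last `cfg$border_exclusion`
#' (5,000) bases of their scaffold are removed: they may represent
#' incomplete genes truncated by the assembly.
#'
#' @param genes Gene-model tibble.
#' @param scaffold_lengths Named integer vector (names = scaffolds) or a
#'   tibble with columns `scaffold` and `length`.
#' @param cfg A [pipeline_config()].
#' @return The retained gene rows.
#' @export
exclude_border_genes <- function(genes, scaffold_lengths,
                                 cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (is.data.frame(scaffold_lengths)) {
    lens <- scaffold_lengths$length
    names(lens) <- scaffold_lengths$scaffold
  } else {
    lens <- scaffold_lengths
  }
  spans <- genes |>
    group_by(.data$gene_id) |>
    summarise(scaffold = .data$scaffold[1L], start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  L <- lens[spans$scaffold]
  if (any(is.na(L))) {
    abort(paste0("unknown scaffold length for: ",
                 spans$scaffold[is.na(L)][1L]))
  }
  b <- cfg$border_exclusion
  hit <- spans$start < b | spans$end > L - b
  genes |> filter(!(.data$gene_id %in% spans$gene_id[hit]))
}

#' Classify how completely an alignment covers a gene's ORF
#'
#' An alignment is `full_orf` when its block union covers every CDS base of
#' the gene, and `full_orf_with_utr` when additionally at least
#' `cfg$full_orf_utr_margin` (10) bases beyond the CDS are covered on both
#' sides (genomic projection); otherwise it is `partial`. Pairs are reported
#' for every alignment overlapping a gene by at least one exon base.
#'
#' @param alignments Spliced-alignment tibble.
#' @param genes Gene-model tibble with CDS coordinates.
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per overlapping (read, transcript) pair:
#'   `read_id`, `transcript_id`, `gene_id`, `orf_class`.
#' @export
classify_orf_coverage <- function(alignments, genes,
                                  cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  m <- cfg$full_orf_utr_margin
  tx <- genes |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(scaffold = .data$scaffold[1L], start = min(.data$start),
              end = max(.data$end), cds_start = .data$cds_start[1L],
              cds_end = .data$cds_end[1L], .groups = "drop")
  if (any(is.na(tx$cds_start))) {
    abort("ORF coverage classification requires CDS coordinates")
  }
  out <- list()
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    ex <- genes |> filter(.data$transcript_id == t$transcript_id)
    blocks <- alignments |> filter(.data$scaffold == t$scaffold,
                                   .data$start < t$end, .data$end > t$start)
    if (!nrow(blocks)) next
    over <- blocks |>
      group_by(.data$read_id) |>
      filter(any(overlap_bases(.data$start, .data$end, ex$start, ex$end) >
                   0)) |>
      ungroup()
    if (!nrow(over)) next
    cds_iv <- ex |>
      mutate(cs = pmax(.data$start, t$cds_start),
             ce = pmin(.data$end, t$cds_end)) |>
      filter(.data$cs < .data$ce)
    cls <- over |>
      group_by(.data$read_id) |>
      summarise(orf_class = {
        # every coding (exonic CDS) base must be covered
        full <- sum(map2_dbl(cds_iv$cs, cds_iv$ce, function(a, b)
          bases_covered(a, b, .data$start, .data$end))) ==
          sum(cds_iv$ce - cds_iv$cs)
        utr <- full &&
          fully_covered(t$cds_start - m, t$cds_start, .data$start,
                        .data$end) &&
          fully_covered(t$cds_end, t$cds_end + m, .data$start, .data$end)
        if (utr) "full_orf_with_utr" else if (full) "full_orf" else "partial"
      }, .groups = "drop")
    out[[length(out) + 1L]] <- cls |>
      mutate(transcript_id = t$transcript_id, gene_id = t$gene_id)
  }
  if (!length(out)) {
    return(tibble(read_id = character(), transcript_id = character(),
                  gene_id = character(), orf_class = character()))
  }
  bind_rows(out) |>
    select("read_id", "transcript_id", "gene_id", "orf_class")
}
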