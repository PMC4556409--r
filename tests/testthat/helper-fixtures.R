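# Small hand-built fixtures used across test files.

make_gene <- function(gene_id = "g1", scaffold = "s1", strand = "+",
                      exons = list(c(100L, 200L), c(300L, 400L)),
                      cds = c(120L, 380L)) {
  ex <- do.call(rbind, exons)
  tibble::tibble(
    gene_id = gene_id,
    transcript_id = paste0(gene_id, ".t1"),
    scaffold = scaffold, strand = strand,
    start = as.integer(ex[, 1]), end = as.integer(ex[, 2]),
    exon_rank = seq_len(nrow(ex)),
    cds_start = if (is.null(cds)) NA_integer_ else as.integer(cds[1]),
    cds_end = if (is.null(cds)) NA_integer_ else as.integer(cds[2]),
    evidence_fraction = NA_real_, attributes = NA_character_
  )
}

make_aln <- function(read_id = "r1", scaffold = "s1", strand = "+",
                     blocks = list(c(100L, 200L), c(300L, 400L)),
                     read_length = NULL, aligned = NULL, identity = 1,
                     n_hits = 1L) {
  b <- do.call(rbind, blocks)
  tot <- sum(b[, 2] - b[, 1])
  tibble::tibble(
    read_id = read_id, scaffold = scaffold, strand = strand,
    start = as.integer(b[, 1]), end = as.integer(b[, 2]),
    block_rank = seq_len(nrow(b)),
    read_length = as.integer(read_length %||% tot),
    aligned_bases = as.integer(aligned %||% tot),
    identity = identity, n_hits = as.integer(n_hits)
  )
}

make_hint <- function(scaffold = "s1", kind = "intron", start = 200L,
                      end = 300L, strand = "+", source = "E",
                      priority = 4L, group = NA_character_, mult = 1L) {
  tibble::tibble(scaffold = scaffold, kind = kind,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, source = source,
                 priority = as.integer(priority), group = group,
                 multiplicity = as.integer(mult))
}

make_cov <- function(scaffold = "s1", from = 0L, depth = rep(10, 100)) {
  tibble::tibble(scaffold = scaffold,
                 pos = as.integer(from + seq_along(depth) - 1L),
                 depth = as.numeric(depth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random coverage + intron-hint fixture with integer depths
random_noise_fixture <- function(seed) {
  withr::with_seed(seed, {
    n_scaf <- sample(1:2, 1)
    cov <- list()
    hints <- list()
    for (s in seq_len(n_scaf)) {
      scaf <- paste0("rs", s)
      len <- sample(1500:2600, 1)
      from <- sample(0:50, 1)
      depth <- sample(0:120, len, replace = TRUE)
      cov[[s]] <- make_cov(scaf, from, depth)
      n_h <- sample(4:9, 1)
      hs <- sort(sample(from:(from + len - 250), n_h))
      hints[[s]] <- make_hint(scaf, "intron", hs,
                              hs + sample(30:200, n_h, replace = TRUE),
                              mult = sample(1:150, n_h, replace = TRUE))
    }
    list(coverage = dplyr::bind_rows(cov),
         hints = dplyr::bind_rows(hints))
  })
}
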