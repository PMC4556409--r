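BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_seq <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Default cDNA synthesis primer pair of the simulator
#'
#' Two synthetic, mutually dissimilar 24-mers standing in for the 5' and 3'
#' template-switch primers of a full-length cDNA protocol.
#'
#' @return Named character vector with elements `p5` and `p3`.
#' @export
default_primers <- function() {
  c(p5 = "ACGGTAGCATTGCAGGACTTCAGT", p3 = "TACGATGCCTAAGTTGCGACTGGT")
}

#' Simulate an annotated genome
#'
#' Generates scaffolds carrying non-overlapping multi-exon protein-coding
#' genes: an `ATG`..stop CDS free of internal stops, `GT`..`AG` introns,
#' and UTRs on both sides. Gene shapes default to the scale of a compact
#' plant genome (around five coding exons per gene, roughly 1 kb of CDS).
#' Each 3' UTR ends on six non-A bases so that the poly(A) boundary of
#' simulated reads is unambiguous under the tail-detection rule. Output is
#' byte-identical for the same seed.
#'
#' @param n_genes Number of genes.
#' @param exon_count_range,intron_len_range,utr_len_range,cds_codon_range
#'   Inclusive integer ranges for exon count per gene, intron length, UTR
#'   length (each side) and protein length in codons.
#' @param intergenic_range Range of intergenic spacer lengths.
#' @param genes_per_scaffold Genes placed per scaffold.
#' @param seed Integer seed.
#' @return A `simulation_truth` list with elements `genome` (named
#'   character vector), `genes` (gene-model tibble), `scaffold_lengths` and
#'   `seed`.
#' @export
simulate_annotated_genome <- function(n_genes = 50,
                                      exon_count_range = c(2L, 8L),
                                      intron_len_range = c(80L, 400L),
                                      utr_len_range = c(60L, 300L),
                                      cds_codon_range = c(110L, 320L),
                                      intergenic_range = c(300L, 800L),
                                      genes_per_scaffold = 25L,
                                      seed = 1L) {
  stopifnot(n_genes >= 0, exon_count_range[1L] >= 1L,
            intron_len_range[1L] >= 10L, utr_len_range[1L] >= 10L)
  withr::local_seed(seed)
  genome <- character()
  scaffold_lengths <- integer()
  gene_rows <- list()
  n_scaf <- if (n_genes == 0L) 0L else
    ceiling(n_genes / genes_per_scaffold)
  gi <- 0L
  for (s in seq_len(n_scaf)) {
    scaf <- sprintf("scaf%02d", s)
    pieces <- list(rand_seq(sample(intergenic_range[1L]:intergenic_range[2L],
                                   1L) + 100L))
    offset <- nchar(pieces[[1L]])
    n_here <- min(genes_per_scaffold, n_genes - gi)
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      g <- simulate_gene(exon_count_range, intron_len_range, utr_len_range,
                         cds_codon_range)
      gene_id <- sprintf("g%04d", gi)
      gene_rows[[gi]] <- tibble(
        gene_id = gene_id,
        transcript_id = paste0(gene_id, ".t1"),
        scaffold = scaf, strand = g$strand,
        start = as.integer(offset + g$exons$start),
        end = as.integer(offset + g$exons$end),
        exon_rank = seq_len(nrow(g$exons)),
        cds_start = as.integer(offset + g$cds[1L]),
        cds_end = as.integer(offset + g$cds[2L]),
        evidence_fraction = NA_real_, attributes = NA_character_)
      pieces[[length(pieces) + 1L]] <- g$seq
      offset <- offset + nchar(g$seq)
      spacer <- rand_seq(sample(intergenic_range[1L]:intergenic_range[2L],
                                1L))
      pieces[[length(pieces) + 1L]] <- spacer
      offset <- offset + nchar(spacer)
    }
    genome[[scaf]] <- paste(unlist(pieces), collapse = "")
    scaffold_lengths[[scaf]] <- nchar(genome[[scaf]])
  }
  structure(list(genome = genome,
                 genes = if (gi) bind_rows(gene_rows) else
                   tibble(gene_id = character(), transcript_id = character(),
                          scaffold = character(), strand = character(),
                          start = integer(), end = integer(),
                          exon_rank = integer(), cds_start = integer(),
                          cds_end = integer(),
                          evidence_fraction = double(),
                          attributes = character()),
                 scaffold_lengths = scaffold_lengths, seed = seed),
            class = "simulation_truth")
}

# One gene in local (sense-layout) coordinates: sequence, exon intervals
# (ascending genomic order), CDS span, strand.
simulate_gene <- function(exon_count_range, intron_len_range,
                          utr_len_range, cds_codon_range,
                          min_exon = 70L) {
  strand <- sample(c("+", "-"), 1L)
  u5 <- sample(utr_len_range[1L]:utr_len_range[2L], 1L)
  u3 <- sample(utr_len_range[1L]:utr_len_range[2L], 1L)
  n_aa <- sample(cds_codon_range[1L]:cds_codon_range[2L], 1L)
  non_stop <- setdiff(mkAllStrings_codons(), STOP_CODONS)
  cds <- paste0("ATG",
                paste(sample(non_stop, n_aa - 1L, replace = TRUE),
                      collapse = ""),
                sample(STOP_CODONS, 1L))
  u3_seq <- paste0(rand_seq(u3 - 6L),
                   paste(sample(c("C", "G", "T"), 6L, replace = TRUE),
                         collapse = ""))
  # stop codons in all three frames just upstream of the ATG, so the
  # longest ORF of the transcript is exactly the annotated CDS
  u5_seq <- paste0(rand_seq(u5 - 11L), "TAAATAAATAA")
  tx <- paste0(u5_seq, cds, u3_seq)
  L <- nchar(tx)
  n_ex <- sample(exon_count_range[1L]:exon_count_range[2L], 1L)
  n_ex <- min(n_ex, max(1L, L %/% min_exon))
  cuts <- integer()
  # keep splice sites >= 12 bases away from the CDS boundaries so the
  # 10-base UTR margins project onto exonic sequence
  forbidden <- c(u5, u5 + nchar(cds))
  if (n_ex > 1L) {
    for (try in 1:200) {
      cuts <- sort(sample(min_exon:(L - min_exon), n_ex - 1L))
      if (all(diff(c(0L, cuts, L)) >= min_exon) &&
          all(abs(outer(cuts, forbidden, "-")) > 12L)) break
      cuts <- integer()
    }
    if (!length(cuts) && n_ex > 1L) n_ex <- 1L
  }
  bounds <- c(0L, cuts, L)
  ex_len <- diff(bounds)
  n_ex <- length(ex_len)
  intron_len <- if (n_ex > 1L) {
    sample(intron_len_range[1L]:intron_len_range[2L], n_ex - 1L,
           replace = TRUE)
  } else integer()
  # local layout
  pieces <- character()
  ex_start <- integer(n_ex)
  loc <- 0L
  for (i in seq_len(n_ex)) {
    ex_start[i] <- loc
    pieces <- c(pieces, substr(tx, bounds[i] + 1L, bounds[i + 1L]))
    loc <- loc + ex_len[i]
    if (i < n_ex) {
      pieces <- c(pieces, paste0("GT", rand_seq(intron_len[i] - 4L), "AG"))
      loc <- loc + intron_len[i]
    }
  }
  gene_seq <- paste(pieces, collapse = "")
  GL <- loc
  t2l <- function(p) {  # transcript position -> local position
    cum <- c(0L, cumsum(ex_len))
    i <- findInterval(p, cum)
    i <- pmin(i, n_ex)
    ex_start[i] + (p - cum[i])
  }
  cds_local <- c(t2l(u5), t2l(u5 + nchar(cds) - 1L) + 1L)
  exons <- tibble(start = ex_start, end = ex_start + ex_len)
  if (strand == "-") {
    gene_seq <- revcomp(gene_seq)
    exons <- tibble(start = GL - exons$end, end = GL - exons$start) |>
      arrange(start)
    cds_local <- c(GL - cds_local[2L], GL - cds_local[1L])
  }
  list(seq = gene_seq, exons = exons, cds = cds_local, strand = strand)
}

mkAllStrings_codons <- function() {
  as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0))
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>",
      sprintf("  %d scaffold(s), %d gene(s)", length(x$genome),
              n_distinct(x$genes$gene_id)), sep = "\n")
  if (!is.null(x$reads)) {
    cat(sprintf("  %d read(s), %d full-insert\n", nrow(x$reads),
                sum(x$labels$full_insert)))
  }
  if (!is.null(x$coverage)) {
    cat(sprintf("  coverage over %d base(s), %d intron hint(s)\n",
                nrow(x$coverage), nrow(x$intron_hints)))
  }
  invisible(x)
}

#' Simulate full-insert cDNA reads with ground-truth alignments
#'
#' Builds reads of the form `P5 + spliced transcript + poly(A) + revcomp(P3)`
#' from an annotated genome. Transcript ends are jittered by up to
#' `boundary_jitter` bases into the genomic flanks/UTRs (emulating variable
#' UTR lengths), point insertions/deletions are applied at `indel_rate`, a
#' configurable fraction of reads lack one primer or the tail (negative
#' labels), and about half the reads are emitted antisense. True spliced
#' alignments are recorded before errors are applied, standing in for an
#' error-free spliced aligner.
#'
#' @param truth A `simulation_truth` from [simulate_annotated_genome()].
#' @param reads_per_gene Reads per gene.
#' @param indel_rate Per-base indel probability in `[0, 0.2]`.
#' @param boundary_jitter Maximum transcript-end jitter in bases.
#' @param primers Named vector `c(p5 = , p3 = )`; see [default_primers()].
#' @param frac_missing_primer,frac_missing_polya Fractions of reads
#'   simulated without one primer / without a tail (labelled not
#'   full-insert).
#' @param antisense_fraction Fraction of reads emitted reverse-complemented.
#' @param polya_len_range Poly(A) tail length range.
#' @param seed Integer seed.
#' @return `truth` extended with `reads` (read tibble), `alignments`
#'   (spliced-alignment tibble of the pre-error inserts), `labels`
#'   (per-read ground truth: `read_id`, `gene_id`, `category`,
#'   `full_insert`, `insert`, `aln_start`, `aln_end`) and `primers`.
#' @export
simulate_full_insert_reads <- function(truth, reads_per_gene = 5L,
                                       indel_rate = 0,
                                       boundary_jitter = 0L,
                                       primers = default_primers(),
                                       frac_missing_primer = 0,
                                       frac_missing_polya = 0,
                                       antisense_fraction = 0.5,
                                       polya_len_range = c(20L, 40L),
                                       seed = 1L) {
  stopifnot(indel_rate >= 0, indel_rate <= 0.2,
            frac_missing_primer + frac_missing_polya <= 1)
  withr::local_seed(seed)
  p5 <- unname(primers[["p5"]]); p3 <- unname(primers[["p3"]])
  p3rc <- revcomp(p3)
  tx <- truth$genes |> group_by(.data$gene_id) |>
    summarise(scaffold = .data$scaffold[1L], strand = .data$strand[1L],
              .groups = "drop")
  reads <- list(); blocks <- list(); labels <- list()
  for (gidx in seq_len(nrow(tx))) {
    gene <- tx$gene_id[gidx]
    ex <- truth$genes |> filter(.data$gene_id == gene) |>
      arrange(.data$start)
    for (r in seq_len(reads_per_gene)) {
      rid <- sprintf("%s_r%02d", gene, r)
      j <- boundary_jitter
      dl <- if (j > 0L) sample(-j:j, 1L) else 0L
      dr <- if (j > 0L) sample(-j:j, 1L) else 0L
      b <- tibble(start = ex$start, end = ex$end)
      b$start[1L] <- b$start[1L] + dl
      b$end[nrow(b)] <- b$end[nrow(b)] + dr
      insert <- extract_transcript(truth$genome, tx$scaffold[gidx], b,
                                   tx$strand[gidx])
      u <- runif(1L)
      category <- if (u < frac_missing_primer) {
        sample(c("no_p5", "no_p3"), 1L)
      } else if (u < frac_missing_primer + frac_missing_polya) {
        "no_polya"
      } else "full"
      tail_seq <- if (category == "no_polya") "" else
        strrep("A", sample(polya_len_range[1L]:polya_len_range[2L], 1L))
      read_seq <- paste0(if (category == "no_p5") "" else p5,
                         insert, tail_seq,
                         if (category == "no_p3") "" else p3rc)
      if (indel_rate > 0) read_seq <- add_indels(read_seq, indel_rate)
      if (runif(1L) < antisense_fraction) read_seq <- revcomp(read_seq)
      reads[[rid]] <- read_seq
      blocks[[rid]] <- b |>
        mutate(read_id = rid, scaffold = tx$scaffold[gidx],
               strand = tx$strand[gidx], block_rank = row_number())
      labels[[rid]] <- tibble(
        read_id = rid, gene_id = gene, category = category,
        full_insert = category == "full", insert = insert,
        aln_start = b$start[1L], aln_end = b$end[nrow(b)])
    }
  }
  aln <- bind_rows(blocks) |>
    group_by(.data$read_id) |>
    mutate(read_length = as.integer(sum(.data$end - .data$start)),
           aligned_bases = .data$read_length, identity = 1,
           n_hits = 1L) |>
    ungroup() |>
    select("read_id", "scaffold", "strand", "start", "end", "block_rank",
           "read_length", "aligned_bases", "identity", "n_hits") |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  truth$reads <- tibble(read_id = names(reads),
                        sequence = unlist(reads, use.names = FALSE),
                        quality = NA_real_, n_passes = 1L)
  truth$alignments <- aln
  truth$labels <- bind_rows(labels)
  truth$primers <- c(p5 = p5, p3 = p3)
  truth
}

add_indels <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  del <- runif(n) < rate / 2
  ins <- runif(n) < rate / 2
  ch[del] <- ""
  if (any(ins)) {
    ch[ins] <- paste0(ch[ins], sample(BASES, sum(ins), replace = TRUE))
  }
  paste(ch, collapse = "")
}

#' Simulate mRNA-seq coverage and intron hints with controlled noise
#'
#' Emulates short-read expression evidence over an annotated genome:
#' exonic depth is Poisson around `exon_depth`, intronic depth is Poisson
#' around `intronic_leak_fraction * exon_depth` (incompletely spliced
#' mRNA), every true intron yields a hint with multiplicity around
#' `exon_depth`, and a fraction of genes additionally produce a weak
#' "rare isoform" intron hint (multiplicity at most `rare_isoform_mult`)
#' overlapping a true intron with shifted boundaries.
#'
#' @param truth A `simulation_truth`.
#' @param exon_depth Mean exonic read depth.
#' @param intronic_leak_fraction Intronic depth as a fraction of
#'   `exon_depth`.
#' @param rare_isoform_mult Maximum multiplicity of noise intron hints.
#' @param noise_intron_fraction Fraction of multi-exon genes receiving one
#'   noise intron hint.
#' @param seed Integer seed.
#' @return `truth` extended with `coverage` (per-base tibble over the
#'   transcribed gene spans) and `intron_hints` (hint tibble with an extra
#'   ground-truth column `truth` in `{"true", "noise"}`).
#' @export
simulate_expression <- function(truth, exon_depth = 100,
                                intronic_leak_fraction = 0.08,
                                rare_isoform_mult = 3L,
                                noise_intron_fraction = 0.5,
                                seed = 1L) {
  stopifnot(exon_depth > 0)
  withr::local_seed(seed)
  cov <- list(); hints <- list()
  for (gene in unique(truth$genes$gene_id)) {
    ex <- truth$genes |> filter(.data$gene_id == gene) |>
      arrange(.data$start)
    scaf <- ex$scaffold[1L]
    span <- ex$start[1L]:(ex$end[nrow(ex)] - 1L)
    exonic <- rep(FALSE, length(span))
    for (i in seq_len(nrow(ex))) {
      exonic[span >= ex$start[i] & span < ex$end[i]] <- TRUE
    }
    depth <- numeric(length(span))
    depth[exonic] <- rpois(sum(exonic), exon_depth)
    depth[!exonic] <- rpois(sum(!exonic),
                            intronic_leak_fraction * exon_depth)
    cov[[gene]] <- tibble(scaffold = scaf, pos = as.integer(span),
                          depth = depth)
    if (nrow(ex) > 1L) {
      d <- head(ex$end, -1L); a <- tail(ex$start, -1L)
      hints[[gene]] <- new_hints(scaf, "intron", d, a, ex$strand[1L], "E",
                                 4L,
                                 multiplicity = pmax(1L, rpois(length(d),
                                                               exon_depth))
                                 ) |>
        mutate(truth = "true", gene_id = gene)
      if (runif(1L) < noise_intron_fraction) {
        k <- sample(length(d), 1L)
        ns <- d[k] + sample(5:15, 1L)
        ne <- a[k] - sample(5:15, 1L)
        if (ns < ne) {
          hints[[paste0(gene, "_noise")]] <-
            new_hints(scaf, "intron", ns, ne, ex$strand[1L], "E", 4L,
                      multiplicity = sample(seq_len(rare_isoform_mult),
                                            1L)) |>
            mutate(truth = "noise", gene_id = gene)
        }
      }
    }
  }
  truth$coverage <- bind_rows(cov) |> arrange(.data$scaffold, .data$pos)
  truth$intron_hints <- if (length(hints)) bind_rows(hints) else
    mutate(empty_hints(), truth = character(), gene_id = character())
  truth
}

#' Corrupt gene models for validation and evaluation tests
#'
#' Applies a logged mixture of structural corruptions: `shift_junction`
#' moves one internal splice junction by `shift` bases (the classic
#' off-by-a-few splice error), `drop_exon` removes one internal exon
#' (fragmented model), and `merge_genes` fuses two neighbouring genes on a
#' scaffold into one model (the transposon-bridge artifact class). Each
#' corruption is logged so downstream outcomes can be checked against
#' ground truth.
#'
#' @param genes Gene-model tibble.
#' @param op_mix Named integer vector of corruption counts, e.g.
#'   `c(shift_junction = 5, drop_exon = 2, merge_genes = 2)`.
#' @param seed Integer seed.
#' @param shift Junction shift in bases for `shift_junction`.
#' @return A list with `genes` (corrupted tibble) and `log` (tibble
#'   `gene_id`, `op`, `detail`).
#' @export
mutate_models <- function(genes, op_mix, seed = 1L, shift = 1L) {
  withr::local_seed(seed)
  g <- genes
  log <- list()
  multi <- g |> count(.data$gene_id) |> filter(.data$n >= 2L) |>
    pull("gene_id")
  pool <- sample(multi)
  n_of <- function(nm) {
    v <- op_mix[nm]
    if (length(v) != 1L || is.na(v)) 0L else as.integer(v)
  }
  take <- function(k) {
    picked <- head(pool, k)
    pool <<- setdiff(pool, picked)
    picked
  }
  for (gene in take(n_of("shift_junction"))) {
    rows <- which(g$gene_id == gene)
    rows <- rows[order(g$start[rows])]
    j <- sample(length(rows) - 1L, 1L)  # junction after exon j
    g$end[rows[j]] <- g$end[rows[j]] + shift
    log[[length(log) + 1L]] <- tibble(gene_id = gene, op = "shift_junction",
                                      detail = paste0("donor+", shift))
  }
  for (gene in take(n_of("drop_exon"))) {
    rows <- which(g$gene_id == gene)
    rows <- rows[order(g$start[rows])]
    if (length(rows) < 3L) next
    drop <- rows[sample(2:(length(rows) - 1L), 1L)]
    g <- g[-drop, , drop = FALSE]
    log[[length(log) + 1L]] <- tibble(gene_id = gene, op = "drop_exon",
                                      detail = "internal exon removed")
  }
  n_merge <- n_of("merge_genes")
  if (n_merge > 0L) {
    spans <- g |> group_by(.data$gene_id) |>
      summarise(scaffold = .data$scaffold[1L], start = min(.data$start),
                .groups = "drop") |>
      arrange(.data$scaffold, .data$start)
    merged <- 0L
    for (i in seq_len(nrow(spans) - 1L)) {
      if (merged >= n_merge) break
      a <- spans$gene_id[i]; b <- spans$gene_id[i + 1L]
      if (spans$scaffold[i] != spans$scaffold[i + 1L]) next
      if (!(a %in% pool) || !(b %in% pool)) next
      pool <- setdiff(pool, c(a, b))
      rows_b <- g$gene_id == b
      cds_a <- g$cds_start[g$gene_id == a][1L]
      cds_ae <- g$cds_end[g$gene_id == a][1L]
      tid_a <- g$transcript_id[g$gene_id == a][1L]
      g$gene_id[rows_b] <- a
      g$transcript_id[rows_b] <- tid_a
      g$cds_start[g$gene_id == a] <- cds_a
      g$cds_end[g$gene_id == a] <- cds_ae
      rows <- which(g$gene_id == a)
      rows <- rows[order(g$start[rows])]
      g$exon_rank[rows] <- seq_along(rows)
      log[[length(log) + 1L]] <- tibble(gene_id = a, op = "merge_genes",
                                        detail = paste0("absorbed ", b))
      merged <- merged + 1L
    }
  }
  list(genes = g |> arrange(.data$scaffold, .data$gene_id, .data$start),
       log = if (length(log)) bind_rows(log) else
         tibble(gene_id = character(), op = character(),
                detail = character()))
}
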