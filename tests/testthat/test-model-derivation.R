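test_that("clustering groups identical chains on overlapping spans", {
  same <- dplyr::bind_rows(lapply(1:3, function(i)
    make_aln(paste0("a", i), blocks = list(c(100L + i, 200L),
                                           c(300L, 400L + i)))))
  cl <- cluster_by_intron_chain(same)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_reads, 3L)
  # chains differing at one junction split into two clusters, one locus
  diff2 <- dplyr::bind_rows(
    make_aln("b1", blocks = list(c(100L, 200L), c(300L, 400L))),
    make_aln("b2", blocks = list(c(100L, 201L), c(300L, 400L))))
  cl2 <- cluster_by_intron_chain(diff2)
  expect_equal(nrow(cl2), 2L)
  expect_equal(dplyr::n_distinct(cl2$locus_id), 1L)
  # intron-free reads on different scaffolds never merge
  sep <- dplyr::bind_rows(
    make_aln("c1", scaffold = "s1", blocks = list(c(0L, 500L))),
    make_aln("c2", scaffold = "s2", blocks = list(c(0L, 500L))))
  expect_equal(nrow(cluster_by_intron_chain(sep)), 2L)
  # opposite strands never share a locus
  strands <- dplyr::bind_rows(
    make_aln("d1", strand = "+", blocks = list(c(0L, 500L))),
    make_aln("d2", strand = "-", blocks = list(c(0L, 500L))))
  cls <- cluster_by_intron_chain(strands)
  expect_equal(dplyr::n_distinct(cls$locus_id), 2L)
})

test_that("clustering partitions the full-length alignments", {
  tr <- simulate_annotated_genome(n_genes = 40, seed = 81)
  tr <- simulate_full_insert_reads(tr, reads_per_gene = 3,
                                   boundary_jitter = 25, seed = 82)
  cl <- cluster_by_intron_chain(tr$alignments)
  members <- unlist(cl$read_ids)
  expect_equal(sort(members), sort(unique(tr$alignments$read_id)))
  expect_equal(anyDuplicated(members), 0L)
})

test_that("most abundant isoform wins; declared tie-breaks apply", {
  big <- dplyr::bind_rows(lapply(1:3, function(i)
    make_aln(paste0("a", i), blocks = list(c(100L, 200L), c(300L, 400L)))))
  small <- make_aln("b1", blocks = list(c(100L, 200L), c(310L, 400L)))
  sel <- select_isoforms(cluster_by_intron_chain(dplyr::bind_rows(big,
                                                                  small)))
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$n_reads, 3L)
  # a lone cluster of two reads qualifies
  two <- dplyr::bind_rows(lapply(1:2, function(i)
    make_aln(paste0("c", i), blocks = list(c(500L, 900L)))))
  expect_equal(nrow(select_isoforms(cluster_by_intron_chain(two))), 1L)
  # 2 vs 2 tie: longer genomic span, then leftmost start
  t1 <- dplyr::bind_rows(lapply(1:2, function(i)
    make_aln(paste0("d", i), blocks = list(c(100L, 200L), c(300L, 420L)))))
  t2 <- dplyr::bind_rows(lapply(1:2, function(i)
    make_aln(paste0("e", i), blocks = list(c(100L, 200L), c(310L, 400L)))))
  sel2 <- select_isoforms(cluster_by_intron_chain(dplyr::bind_rows(t1, t2)))
  expect_equal(sel2$span_end, 420L)
})

test_that("single spliced reads qualify only with confirmed junctions", {
  lone <- make_aln("x", blocks = list(c(100L, 200L), c(300L, 400L)))
  cl <- cluster_by_intron_chain(lone)
  expect_equal(nrow(select_isoforms(cl)), 0L)
  evid <- tibble::tibble(scaffold = "s1", start = 200L, end = 300L)
  expect_equal(nrow(select_isoforms(cl, intron_evidence = evid)), 1L)
  wrong <- tibble::tibble(scaffold = "s1", start = 201L, end = 300L)
  expect_equal(nrow(select_isoforms(cl, intron_evidence = wrong)), 0L)
  # an intron-free singleton never qualifies through evidence
  free <- cluster_by_intron_chain(make_aln("y", blocks = list(c(0L, 300L))))
  expect_equal(nrow(select_isoforms(free, intron_evidence = evid)), 0L)
})

test_that("boundaries are lower medians of member spans", {
  mk <- function(starts, ends) {
    tibble::tibble(cluster_id = "c", starts = list(starts),
                   ends = list(ends))
  }
  expect_equal(derive_boundaries(mk(1000L, 3000L))$start, 1000L)
  expect_equal(derive_boundaries(mk(c(100L, 110L, 130L),
                                    c(900L, 910L, 930L)))$start, 110L)
  expect_equal(derive_boundaries(mk(c(100L, 120L), c(900L, 920L)))$start,
               100L)
  expect_equal(derive_boundaries(mk(c(100L, 120L), c(900L, 920L)))$end,
               900L)
})

test_that("longest forward-frame ORF is called, matching exhaustive scan", {
  o <- find_orf("ATGAAATAA", min_codons = 1)
  expect_equal(c(o$start, o$end), c(0L, 9L))
  expect_equal(o$protein, "MK")
  # the longer of two ORFs wins
  orf33 <- paste0("ATG", strrep("GCT", 32), "TAA")
  orf96 <- paste0("ATG", strrep("GAA", 95), "TGA")
  s <- paste0("CC", orf33, "TTT", orf96, "GG")
  o2 <- find_orf(s, min_codons = 10)
  expect_equal(o2$end - o2$start, nchar(orf96))
  expect_equal(substr(s, o2$start + 1, o2$start + 3), "ATG")
  expect_equal(nrow(find_orf("CCCTTTGGGCCCTTT", min_codons = 1)), 0L)
  # agreement with a brute-force scan on random sequences
  withr::with_seed(83, {
    for (i in 1:25) {
      s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
      got <- find_orf(s, min_codons = 5)
      want <- oracle_find_orf(s, min_codons = 5)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got$end - got$start, want$end - want$start)
      }
    }
  })
})

test_that("derived models recover simulated genes exactly", {
  tr <- simulate_annotated_genome(n_genes = 30, seed = 84)
  tr <- simulate_full_insert_reads(tr, reads_per_gene = 4,
                                   boundary_jitter = 30, seed = 85)
  dm <- derive_gene_models(tr$alignments, tr$genome)
  expect_equal(dplyr::n_distinct(dm$gene_id), 30L)
  ck_t <- smartanno:::chain_keys(tr$genes, "transcript_id")
  ck_d <- smartanno:::chain_keys(dm, "transcript_id")
  expect_setequal(ck_d$chain_key, ck_t$chain_key)
  expect_true(all(!is.na(dm$cds_start)))
  # derived CDS span matches the annotated CDS (ORF recovered)
  truth_cds <- tr$genes |>
    dplyr::distinct(gene_id, scaffold, cds_start, cds_end) |>
    dplyr::arrange(scaffold, cds_start)
  derived_cds <- dm |>
    dplyr::distinct(gene_id, scaffold, cds_start, cds_end) |>
    dplyr::arrange(scaffold, cds_start)
  expect_equal(derived_cds$cds_start, truth_cds$cds_start)
  expect_equal(derived_cds$cds_end, truth_cds$cds_end)
})

test_that("candidates overlapping existing genes are dropped; empty input is empty", {
  tr <- simulate_annotated_genome(n_genes = 10, seed = 86)
  tr <- simulate_full_insert_reads(tr, reads_per_gene = 3, seed = 87)
  existing <- tr$genes |> dplyr::filter(gene_id %in%
                                          sprintf("g%04d", 1:5))
  dm <- derive_gene_models(tr$alignments, tr$genome, existing = existing)
  expect_equal(dplyr::n_distinct(dm$gene_id), 5L)
  olap <- dplyr::inner_join(dm, existing, by = "scaffold",
                            relationship = "many-to-many",
                            suffix = c("", ".e")) |>
    dplyr::filter(start < end.e, end > start.e)
  expect_equal(nrow(olap), 0L)
  empty <- derive_gene_models(tr$alignments[0, ], tr$genome)
  expect_equal(nrow(empty), 0L)
})

test_that("adding reads to the winning isoform never changes the chain", {
  base <- dplyr::bind_rows(lapply(1:3, function(i)
    make_aln(paste0("a", i), blocks = list(c(100L, 200L), c(300L, 400L)))))
  rival <- dplyr::bind_rows(lapply(1:2, function(i)
    make_aln(paste0("b", i), blocks = list(c(100L, 201L), c(300L, 400L)))))
  sel1 <- select_isoforms(cluster_by_intron_chain(dplyr::bind_rows(base,
                                                                   rival)))
  extra <- make_aln("a9", blocks = list(c(100L, 200L), c(300L, 400L)))
  sel2 <- select_isoforms(cluster_by_intron_chain(
    dplyr::bind_rows(base, rival, extra)))
  expect_equal(sel2$chain, sel1$chain)
  expect_equal(sel2$n_reads, sel1$n_reads + 1L)
})
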