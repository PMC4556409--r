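test_that("the simulator is fully deterministic per seed", {
  a <- simulate_annotated_genome(n_genes = 10, seed = 121)
  b <- simulate_annotated_genome(n_genes = 10, seed = 121)
  expect_identical(a$genome, b$genome)
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  a <- simulate_full_insert_reads(a, reads_per_gene = 3, indel_rate = 0.03,
                                  boundary_jitter = 20, seed = 122)
  b <- simulate_full_insert_reads(b, reads_per_gene = 3, indel_rate = 0.03,
                                  boundary_jitter = 20, seed = 122)
  expect_identical(a$reads$sequence, b$reads$sequence)
  a <- simulate_expression(a, seed = 123)
  b <- simulate_expression(b, seed = 123)
  expect_identical(a$coverage$depth, b$coverage$depth)
  c <- simulate_annotated_genome(n_genes = 10, seed = 124)
  expect_false(identical(a$genome, c$genome))
  expect_equal(nrow(simulate_annotated_genome(n_genes = 0, seed = 1)$genes),
               0L)
})

test_that("every generated CDS translates without internal stops", {
  tr <- simulate_annotated_genome(n_genes = 20, seed = 125)
  for (tid in unique(tr$genes$transcript_id)) {
    ex <- tr$genes[tr$genes$transcript_id == tid, ]
    cex <- tibble::tibble(start = pmax(ex$start, ex$cds_start[1]),
                          end = pmin(ex$end, ex$cds_end[1]))
    cex <- cex[cex$start < cex$end, ]
    cds <- smartanno:::extract_transcript(tr$genome, ex$scaffold[1], cex,
                                          ex$strand[1])
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  # introns are canonical GT..AG
  ic <- intron_chains(tr$genes)
  for (i in seq_len(nrow(ic))) {
    intr <- substr(tr$genome[[ic$scaffold[i]]], ic$start[i] + 1,
                   ic$end[i])
    if (ic$strand[i] == "-") {
      intr <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(intr)))
    }
    expect_equal(substr(intr, 1, 2), "GT")
    expect_equal(substr(intr, nchar(intr) - 1, nchar(intr)), "AG")
  }
})

test_that("simulated data pass cleanly through the parsers", {
  tr <- simulate_annotated_genome(n_genes = 8, seed = 126)
  tr <- simulate_full_insert_reads(tr, reads_per_gene = 2, seed = 127)
  tr <- simulate_expression(tr, seed = 128)
  d <- withr::local_tempdir()
  write_fasta(tr$genome, file.path(d, "genome.fasta"))
  write_gff3_genes(tr$genes, file.path(d, "genes.gff3"))
  write_gff3_alignments(tr$alignments, file.path(d, "aln.gff3"))
  write_wiggle(tr$coverage, file.path(d, "cov.wig"))
  write_hints(dplyr::select(tr$intron_hints, -truth, -gene_id),
              file.path(d, "introns.gff"))
  expect_identical(read_fasta(file.path(d, "genome.fasta")), tr$genome)
  expect_equal(as.data.frame(read_gff3_genes(file.path(d, "genes.gff3"))),
               as.data.frame(tr$genes))
  expect_equal(nrow(read_gff3_alignments(file.path(d, "aln.gff3"))),
               nrow(tr$alignments))
  expect_equal(as.data.frame(read_wiggle(file.path(d, "cov.wig"))),
               as.data.frame(tr$coverage))
  expect_equal(nrow(read_hints(file.path(d, "introns.gff"))),
               nrow(tr$intron_hints))
})

test_that("model corruptions are logged and detectable downstream", {
  tr <- simulate_annotated_genome(n_genes = 20, seed = 129)
  tr <- simulate_full_insert_reads(tr, reads_per_gene = 3, seed = 130)
  mm <- mutate_models(tr$genes, c(shift_junction = 4, drop_exon = 2,
                                  merge_genes = 2), seed = 131)
  expect_equal(sum(mm$log$op == "shift_junction"), 4L)
  st <- validate_gene_models(mm$genes, tr$alignments)
  shifted <- mm$log$gene_id[mm$log$op == "shift_junction"]
  expect_true(all(st$status[st$gene_id %in% shifted] == "contradicted"))
  # merged models have no exact transcript match in the truth
  merged <- mm$log$gene_id[mm$log$op == "merge_genes"]
  if (length(merged)) {
    ev <- evaluate_predictions(mm$genes[mm$genes$gene_id %in% merged, ],
                               tr$genes)
    expect_equal(ev$tp[ev$level == "transcript"], 0L)
  }
  none <- mutate_models(tr$genes, c(shift_junction = 0), seed = 1)
  expect_identical(as.data.frame(none$genes),
                   as.data.frame(dplyr::arrange(tr$genes, scaffold,
                                                gene_id, start)))
})

test_that("classify-derive-hints runs end to end on a small genome", {
  tr <- simulate_annotated_genome(n_genes = 20, seed = 132)
  tr <- simulate_full_insert_reads(tr, reads_per_gene = 3,
                                   indel_rate = 0.05, seed = 133)
  cl <- classify_reads(tr$reads, tr$primers[["p5"]], tr$primers[["p3"]])
  expect_gte(mean(cl$full_insert == tr$labels$full_insert), 0.95)
  dm <- derive_gene_models(tr$alignments, tr$genome)
  ck_t <- smartanno:::chain_keys(tr$genes, "transcript_id")
  ck_d <- smartanno:::chain_keys(dm, "transcript_id")
  expect_gte(mean(ck_t$chain_key %in% ck_d$chain_key), 0.95)
  sel <- derive_boundaries(select_isoforms(cluster_by_intron_chain(
    tr$alignments)))
  h <- add_flanking_intergenic_hints(isoform_to_hints(sel),
                                     tr$scaffold_lengths)
  expect_gte(sum(h$kind == "irpart"), 2L * 0.9 * 20L)
  f <- withr::local_tempfile()
  write_hints(h, f)
  expect_equal(nrow(read_hints(f)), nrow(h))
})
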