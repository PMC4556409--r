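test_that("GFF3 gene parsing converts 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
    "s1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "s1\tsrc\texon\t101\t200\t.\t+\t.\tParent=g1.t1",
    "s1\tsrc\texon\t301\t400\t.\t+\t.\tParent=g1.t1",
    "s1\tsrc\tCDS\t121\t200\t.\t+\t0\tParent=g1.t1",
    "s1\tsrc\tCDS\t301\t380\t.\t+\t1\tParent=g1.t1"
  ), f)
  g <- read_gff3_genes(f)
  expect_equal(nrow(g), 2L)
  expect_equal(g$start, c(100L, 300L))
  expect_equal(g$end, c(200L, 400L))
  expect_equal(g$cds_start, c(120L, 120L))
  expect_equal(g$cds_end, c(380L, 380L))
  ic <- intron_chains(g)
  expect_equal(nrow(ic), 1L)
  expect_equal(c(ic$start, ic$end), c(200L, 300L))
})

test_that("empty or header-only GFF3 yields an empty model set", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  expect_equal(nrow(read_gff3_genes(f)), 0L)
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(read_gff3_genes(f), f2)
  expect_equal(readLines(f2), "##gff-version 3")
})

test_that("GFF3 parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\tsrc\tgene\t101\t400\t.\t+\t.",
               "s1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1"), f)
  expect_error(read_gff3_genes(f), "line 2")
  writeLines(c("s1\tsrc\tmRNA\t500\t400\t.\t+\t.\tID=t1"), f)
  expect_error(read_gff3_genes(f), "line 1")
  writeLines(c("s1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=nope",
               "s1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1"), f)
  expect_error(read_gff3_genes(f), "unknown parent")
  writeLines(c("s1\tsrc\texon\t101\t400\t.\t+\t.\tParent=ghost"), f)
  expect_error(read_gff3_genes(f), "line 1.*unknown parent")
})

test_that("gene model GFF3 round trip is lossless, attributes preserved", {
  tr <- simulate_annotated_genome(n_genes = 30, seed = 21)
  g <- tr$genes
  tx <- unique(g$transcript_id)
  g$evidence_fraction[g$transcript_id %in% tx[1:5]] <-
    rep(c(1, 0.5, 0.25, 0.8, 0), table(g$transcript_id)[tx[1:5]])
  g$attributes[g$transcript_id %in% tx[6:9]] <- "note=kept;foo=bar"
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(g, f)
  g2 <- read_gff3_genes(f)
  expect_equal(as.data.frame(g2), as.data.frame(g))
  # emission is 1-based inclusive: exon (100,200) prints as 101..200
  f3 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(make_gene(exons = list(c(100L, 200L)), cds = NULL), f3)
  expect_true(any(grepl("\texon\t101\t200\t", readLines(f3))))
})

test_that("alignment GFF3 round trip preserves block and read-level data", {
  a <- dplyr::bind_rows(
    make_aln("r1", blocks = list(c(10L, 60L), c(100L, 150L)),
             read_length = 110L, aligned = 100L, identity = 0.97),
    make_aln("r2", scaffold = "s2", strand = "-",
             blocks = list(c(5L, 45L)), n_hits = 2L))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_alignments(a, f)
  a2 <- read_gff3_alignments(f)
  expect_equal(as.data.frame(a2), as.data.frame(dplyr::arrange(
    a, scaffold, read_id, start)))
})

test_that("wiggle fixedStep and variableStep parse to 0-based tracks", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("track type=wiggle_0",
               "fixedStep chrom=chr1 start=11 step=1 span=1",
               "5", "5", "5"), f)
  w <- read_wiggle(f)
  expect_equal(w$pos, c(10L, 11L, 12L))
  expect_equal(w$depth, c(5, 5, 5))
  writeLines(c("variableStep chrom=chr1",
               "11\t4", "12\t4", "40\t7"), f)
  w2 <- read_wiggle(f)
  tracks <- smartanno:::coverage_tracks(w2)
  expect_equal(dplyr::n_distinct(tracks$track), 2L)
  writeLines(c("fixedStep chrom=chr1 start=5 step=1",
               "3", "-1"), f)
  expect_error(read_wiggle(f), "negative")
})

test_that("wiggle round trip is lossless, including fractional depths", {
  withr::with_seed(31, {
    cov <- dplyr::bind_rows(
      make_cov("c1", 10L, sample(0:50, 400, replace = TRUE)),
      make_cov("c1", 900L, sample(0:50, 100, replace = TRUE)),
      make_cov("c2", 0L, round(stats::runif(80, 0, 20), 3)))
  })
  f <- withr::local_tempfile(fileext = ".wig")
  write_wiggle(cov, f)
  expect_equal(as.data.frame(read_wiggle(f)),
               as.data.frame(dplyr::arrange(cov, scaffold, pos)))
})

test_that("hint dialect parses src/pri/grp/mult with defaults and vocab", {
  f <- withr::local_tempfile(fileext = ".gff")
  writeLines(c("s1\tw2h\tnonexonpart\t101\t200\t.\t.\t.\tsrc=RM;pri=6",
               "s1\tw2h\tintron\t301\t400\t.\t+\t.\tsrc=E;mult=12;grp=a"),
             f)
  h <- read_hints(f)
  expect_equal(h$source, c("RM", "E"))
  expect_equal(h$priority, c(6L, NA_integer_))
  expect_equal(h$multiplicity, c(1L, 12L))  # missing mult defaults to 1
  expect_equal(h$start, c(100L, 300L))
  writeLines("s1\tw2h\tpromoter\t1\t10\t.\t.\t.\tsrc=E", f)
  expect_error(read_hints(f), "unknown hint kind")
  writeLines("s1\tw2h\texon\t1\t10\t.\t.\t.\tsrc=XX", f)
  expect_error(read_hints(f), "unknown hint source")
})

test_that("hint round trip is lossless and permutation stable", {
  withr::with_seed(41, {
    n <- 60
    h <- make_hint(scaffold = sample(c("s1", "s2"), n, replace = TRUE),
                   kind = sample(smartanno:::HINT_KINDS, n, replace = TRUE),
                   start = sample(0:5000, n),
                   end = 0L, strand = sample(c("+", "-", "."), n, TRUE),
                   source = sample(c("E", "M", "RM"), n, TRUE),
                   priority = sample(1:9, n, TRUE),
                   group = sample(c(NA, "grp1", "grp2"), n, TRUE),
                   mult = sample(1:200, n, TRUE))
    h$end <- h$start + sample(1:500, n, TRUE)
  })
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hints(h, f1)
  write_hints(h[sample(nrow(h)), ], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(as.data.frame(read_hints(f1)),
               as.data.frame(smartanno:::sort_hints(h)))
})

test_that("parsed intervals always satisfy 0 <= start < end, chains have k-1 introns", {
  tr <- simulate_annotated_genome(n_genes = 25, seed = 51)
  f <- withr::local_tempfile()
  write_gff3_genes(tr$genes, f)
  g <- read_gff3_genes(f)
  expect_true(all(g$start >= 0 & g$start < g$end))
  ic <- intron_chains(g)
  k <- dplyr::count(g, transcript_id)
  ni <- dplyr::count(ic, transcript_id)
  joined <- dplyr::left_join(k, ni, by = "transcript_id",
                             suffix = c("_ex", "_in"))
  joined$n_in[is.na(joined$n_in)] <- 0L
  expect_equal(joined$n_in, joined$n_ex - 1L)
})
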