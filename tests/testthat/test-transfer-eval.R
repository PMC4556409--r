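genes_as_old_alignments <- function(genes, shift = 0L) {
  genes |>
    dplyr::mutate(cs = pmax(start, cds_start), ce = pmin(end, cds_end)) |>
    dplyr::filter(cs < ce) |>
    dplyr::transmute(old_id = gene_id, scaffold,
                     start = cs + shift, end = ce + shift)
}

test_that("identical annotations transfer every id, no fresh ids", {
  g <- dplyr::bind_rows(
    make_gene("a", exons = list(c(100L, 300L)), cds = c(150L, 250L)),
    make_gene("b", exons = list(c(500L, 800L)), cds = c(520L, 700L)),
    make_gene("c", exons = list(c(1000L, 1400L)), cds = c(1100L, 1300L)))
  res <- transfer_stable_ids(genes_as_old_alignments(g), g)
  expect_equal(res$stable_id, res$new_id)
  expect_equal(res$old_id, res$new_id)
  expect_length(attr(res, "unassigned_old"), 0L)
})

test_that("one old gene over two new genes: longest partial overlap wins", {
  old <- tibble::tibble(old_id = "old1", scaffold = "s1",
                        start = 100L, end = 1100L)
  new <- dplyr::bind_rows(
    make_gene("A", exons = list(c(100L, 900L)), cds = c(100L, 900L)),
    make_gene("B", exons = list(c(900L, 1300L)), cds = c(900L, 1300L)))
  res <- transfer_stable_ids(old, new)
  expect_equal(res$stable_id[res$new_id == "A"], "old1")  # 800 vs 200 bases
  expect_true(startsWith(res$stable_id[res$new_id == "B"], "NEWGENE_"))
})

test_that("many old genes on one new gene: reciprocal best wins, rest unassigned", {
  old <- dplyr::bind_rows(
    tibble::tibble(old_id = "X", scaffold = "s1", start = 100L, end = 1000L),
    tibble::tibble(old_id = "Y", scaffold = "s1", start = 150L, end = 1050L))
  new <- make_gene("Z", exons = list(c(100L, 1100L)), cds = c(100L, 1100L))
  res <- transfer_stable_ids(old, new)
  expect_equal(res$stable_id, "X")  # X overlaps Z by 900, Y by 900 - tie
  expect_true("Y" %in% attr(res, "unassigned_old"))
  expect_error(transfer_stable_ids(
    tibble::tibble(old_id = "X", scaffold = c("s1", "s2"),
                   start = c(0L, 0L), end = c(10L, 10L)), new),
    "duplicate")
})

test_that("transfer is injective and translation invariant", {
  tr <- simulate_annotated_genome(n_genes = 20, seed = 111)
  old <- genes_as_old_alignments(tr$genes)
  withr::with_seed(112, {
    keep <- sample(unique(tr$genes$gene_id), 16)
  })
  new <- tr$genes |> dplyr::filter(gene_id %in% keep) |>
    dplyr::mutate(gene_id = paste0("N_", gene_id))
  res <- transfer_stable_ids(old, new)
  expect_equal(anyDuplicated(res$stable_id), 0L)
  expect_equal(anyDuplicated(stats::na.omit(res$old_id)), 0L)
  shifted_old <- old |> dplyr::mutate(start = start + 7777L,
                                      end = end + 7777L)
  shifted_new <- new |> dplyr::mutate(start = start + 7777L,
                                      end = end + 7777L,
                                      cds_start = cds_start + 7777L,
                                      cds_end = cds_end + 7777L)
  res2 <- transfer_stable_ids(shifted_old, shifted_new)
  expect_equal(res2$old_id, res$old_id)
})

test_that("evaluating a reference against itself scores 1 everywhere", {
  tr <- simulate_annotated_genome(n_genes = 15, seed = 113)
  ev <- evaluate_predictions(tr$genes, tr$genes)
  expect_equal(ev$sensitivity, rep(1, 3))
  expect_equal(ev$precision, rep(1, 3))
  expect_true(all(ev$precision_defined))
  g <- glance(ev)
  expect_equal(g$accuracy_sum, 4)
})

test_that("the 3-of-4 reference / 3-of-5 predicted exon case scores 0.75 / 0.60", {
  ref <- make_gene("r", exons = list(c(100L, 200L), c(300L, 400L),
                                     c(500L, 600L), c(700L, 800L)),
                   cds = c(120L, 780L))
  pred <- make_gene("p", exons = list(c(100L, 200L), c(300L, 400L),
                                      c(500L, 600L), c(650L, 680L),
                                      c(700L, 790L)),
                    cds = c(120L, 780L))
  ev <- evaluate_predictions(pred, ref)
  expect_equal(ev$sensitivity[ev$level == "exon"], 0.75)
  expect_equal(ev$precision[ev$level == "exon"], 0.60)
  expect_equal(ev$sensitivity[ev$level == "transcript"], 0)
})

test_that("empty predictions give zero precision with an explicit flag", {
  ref <- make_gene("r")
  ev <- evaluate_predictions(ref[0, ], ref)
  expect_equal(ev$sensitivity, rep(0, 3))
  expect_equal(ev$precision, rep(0, 3))
  expect_false(any(ev$precision_defined))
})

test_that("exon/transcript metrics agree with a brute-force set oracle", {
  withr::with_seed(114, {
    for (i in 1:20) {
      tr <- simulate_annotated_genome(n_genes = 8,
                                      seed = sample.int(10000, 1))
      pred <- tr$genes
      drop <- sample(unique(pred$gene_id), 2)
      pred <- pred[!(pred$gene_id %in% drop), ]
      jit <- sample(nrow(pred), 3)
      pred$end[jit] <- pred$end[jit] + 1L
      ev <- evaluate_predictions(pred, tr$genes)
      want <- oracle_eval(pred, tr$genes)
      expect_equal(ev$sensitivity[ev$level == "exon"], want$exon_sn)
      expect_equal(ev$precision[ev$level == "exon"], want$exon_sp)
      expect_equal(ev$sensitivity[ev$level == "transcript"], want$tx_sn)
      expect_equal(ev$precision[ev$level == "transcript"], want$tx_sp)
    }
  })
})

test_that("training gene selection removes frame-broken and redundant genes", {
  g <- dplyr::bind_rows(
    make_gene("ok1", exons = list(c(0L, 500L)), cds = c(100L, 400L)),
    make_gene("bad3", exons = list(c(1000L, 1500L)), cds = c(1000L, 1301L)),
    make_gene("ok2", exons = list(c(2000L, 2500L)), cds = c(2000L, 2240L)),
    make_gene("ok3", exons = list(c(3000L, 3500L)), cds = c(3000L, 3120L)))
  idn <- tibble::tibble(id1 = "ok2", id2 = "ok3", identity = 0.80)
  split1 <- select_training_genes(g, idn, 1, 1, seed = 7)
  picked <- c(split1$train, split1$test)
  expect_false("bad3" %in% picked)   # CDS length 301 not divisible by 3
  expect_false("ok3" %in% picked)    # 0.80 is redundant, shorter CDS drops
  expect_setequal(picked, c("ok1", "ok2"))
  split2 <- select_training_genes(g, idn, 1, 1, seed = 7)
  expect_identical(split1, split2)
  below <- tibble::tibble(id1 = "ok2", id2 = "ok3", identity = 0.79)
  expect_no_error(select_training_genes(g, below, 2, 1, seed = 7))
})

test_that("selected training sets are redundancy-free under the identity table", {
  withr::with_seed(115, {
    n <- 30
    g <- dplyr::bind_rows(lapply(seq_len(n), function(i)
      make_gene(sprintf("g%02d", i),
                exons = list(c(i * 1000L, i * 1000L + 500L)),
                cds = c(i * 1000L, i * 1000L + 3L * sample(50:120, 1)))))
    idn <- tibble::tibble(
      id1 = sprintf("g%02d", sample(n, 40, TRUE)),
      id2 = sprintf("g%02d", sample(n, 40, TRUE)),
      identity = round(stats::runif(40, 0.5, 1), 2)) |>
      dplyr::filter(id1 != id2)
  })
  sel <- select_training_genes(g, idn, 5, 3, seed = 8)
  surv <- c(sel$train, sel$test)
  clash <- idn |> dplyr::filter(identity >= 0.8, id1 %in% surv,
                                id2 %in% surv)
  expect_equal(nrow(clash), 0L)
})

test_that("reciprocal best hits follow the filter and mutual-best rules", {
  ab <- tibble::tibble(query = c("a1", "a1", "a2"),
                       subject = c("b1", "b2", "b1"),
                       evalue = c(1e-30, 1e-10, 1e-20),
                       bitscore = c(500, 100, 300),
                       alignment_length = c(200, 180, 150), qlen = 220)
  ba <- tibble::tibble(query = c("b1", "b2"), subject = c("a1", "a1"),
                       evalue = c(1e-28, 1e-9), bitscore = c(480, 90),
                       alignment_length = c(210, 170), qlen = 230)
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(rbh), 1L)
  expect_equal(c(rbh$a, rbh$b), c("a1", "b1"))
  # a -> b best but b -> c best: no pair
  ba2 <- ba; ba2$subject <- c("a9", "a1")
  expect_equal(nrow(reciprocal_best_hits(ab, ba2)), 0L)
  # alignment shorter than half the query is filtered out
  ab3 <- ab; ab3$alignment_length <- 80
  expect_equal(nrow(reciprocal_best_hits(ab3, ba)), 0L)
})

test_that("stress-specific genes need zero control and >=90% stress coverage", {
  cov <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 4),
    condition = rep(c("control", "salt", "heat", "light"), 3),
    coverage = c(0, 0.95, 0.2, 0,
                 0.01, 1, 1, 1,
                 0, 0.85, 0.7, 0.3))
  expect_equal(stress_specific_genes(cov), "g1")
  expect_error(stress_specific_genes(dplyr::mutate(cov,
                                                   coverage = coverage * 2)),
               "0, 1")
})

test_that("alignment accuracy averages identities of full-length alignments", {
  a <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                      read_length = c(1000L, 1000L, 1000L),
                      aligned_bases = c(950L, 990L, 850L),
                      identity = c(0.97, 0.99, 0.50))
  expect_equal(alignment_accuracy(a), 0.98)
  # best alignment per read is chosen before filtering
  b <- dplyr::bind_rows(a[1, ],
                        tibble::tibble(read_id = "r1",
                                       read_length = 1000L,
                                       aligned_bases = 990L,
                                       identity = 0.999))
  expect_equal(alignment_accuracy(b), 0.999)
  expect_error(alignment_accuracy(a[0, ]), "no qualifying")
})
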