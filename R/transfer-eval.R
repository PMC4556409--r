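#' Transfer stable gene identifiers between annotation versions
#'
#' Each old gene's identifier moves to the new gene with the longest summed
#' CDS match length (overlap in bases between the old gene's aligned CDS
#' blocks and the new gene's CDS regions). When one old gene overlaps
#' several new genes, the longest partial overlap wins and the other new
#' genes receive fresh identifiers; when several old genes match one new
#' gene best, the reciprocal best match (the old gene with the largest
#' overlap to that new gene) wins and the others remain unassigned. Equal
#' overlaps are resolved greedily left-to-right along the scaffold so that
#' gene order is preserved. New genes without a transferred identifier get
#' fresh ids in positional order.
#'
#' @param old_alignments Placements of old CDSs on the new assembly: a
#'   tibble with one row per aligned block and columns `old_id`,
#'   `scaffold`, `start`, `end`.
#' @param new_genes Gene-model tibble of the new annotation.
#' @return A tibble with one row per new gene: `new_id`, `stable_id`,
#'   `old_id` (`NA` where a fresh id was assigned). Old ids that could not
#'   be placed are available as `attr(result, "unassigned_old")`.
#' @export
transfer_stable_ids <- function(old_alignments, new_genes) {
  old <- old_alignments |>
    group_by(.data$old_id) |>
    summarise(n_scaf = n_distinct(.data$scaffold),
              scaffold = .data$scaffold[1L],
              span_start = min(.data$start), span_end = max(.data$end),
              .groups = "drop")
  if (any(old$n_scaf > 1L)) {
    abort(paste0("duplicate old id on multiple scaffolds: ",
                 old$old_id[old$n_scaf > 1L][1L]))
  }
  new_cds <- new_genes |>
    mutate(cs = pmax(.data$start, coalesce(.data$cds_start, .data$start)),
           ce = pmin(.data$end, coalesce(.data$cds_end, .data$end))) |>
    filter(.data$cs < .data$ce)
  new_spans <- new_cds |>
    group_by(.data$gene_id) |>
    summarise(scaffold = .data$scaffold[1L], span_start = min(.data$cs),
              span_end = max(.data$ce), .groups = "drop") |>
    arrange(.data$scaffold, .data$span_start)

  # candidate pairs by span overlap, then exact summed CDS overlap
  cand <- old |>
    inner_join(new_spans |> rename(new_id = "gene_id", ns = "span_start",
                                   ne = "span_end"),
               by = "scaffold", relationship = "many-to-many") |>
    filter(.data$span_start < .data$ne, .data$span_end > .data$ns)
  if (nrow(cand)) {
    cand$overlap <- map_dbl(seq_len(nrow(cand)), function(i) {
      ob <- old_alignments |> filter(.data$old_id == cand$old_id[i])
      nb <- new_cds |> filter(.data$gene_id == cand$new_id[i])
      overlap_bases(ob$start, ob$end, nb$cs, nb$ce)
    })
    cand <- cand |> filter(.data$overlap > 0)
  }

  assigned <- tibble(old_id = character(), new_id = character())
  if (nrow(cand)) {
    # best new gene per old gene; ties resolved left-to-right in old order
    old_order <- old |> arrange(.data$scaffold, .data$span_start)
    claimed <- character()
    best <- list()
    for (oid in old_order$old_id) {
      cc <- cand |> filter(.data$old_id == oid)
      if (!nrow(cc)) next
      cc <- cc |> filter(.data$overlap == max(.data$overlap)) |>
        arrange(.data$ns, .data$new_id)
      free <- cc |> filter(!(.data$new_id %in% claimed))
      pick <- if (nrow(free)) free$new_id[1L] else cc$new_id[1L]
      claimed <- c(claimed, pick)
      best[[oid]] <- tibble(old_id = oid, new_id = pick,
                            overlap = cc$overlap[1L])
    }
    best <- bind_rows(best)
    # reciprocal resolution: one winner per new gene
    if (nrow(best)) {
      old_rank <- match(best$old_id, old_order$old_id)
      assigned <- best |>
        mutate(rank = old_rank) |>
        group_by(.data$new_id) |>
        arrange(desc(.data$overlap), .data$rank, .by_group = TRUE) |>
        slice(1L) |>
        ungroup() |>
        select("old_id", "new_id")
    }
  }
  out <- new_spans |>
    rename(new_id = "gene_id") |>
    left_join(assigned, by = "new_id") |>
    arrange(.data$scaffold, .data$span_start)
  fresh <- is.na(out$old_id)
  out$stable_id <- out$old_id
  out$stable_id[fresh] <- sprintf("NEWGENE_%06d", seq_len(sum(fresh)))
  res <- out |> select("new_id", "stable_id", "old_id")
  attr(res, "unassigned_old") <- setdiff(old$old_id, assigned$old_id)
  res
}

#' Evaluate gene predictions against a reference
#'
#' Sensitivity and precision at three feature levels: `exon` (true positive
#' = exact coordinate and strand match), `transcript` (all exons match
#' exactly) and `utr_base` (per-base agreement of the UTR annotation, i.e.
#' exon regions outside the CDS span). Sensitivity divides true positives
#' by all reference features; precision divides them by all predicted
#' features within the evaluation `regions` (all predicted features when
#' `regions` is `NULL`). An empty prediction yields precision 0 with
#' `precision_defined = FALSE` rather than `NaN`.
#'
#' @param predicted,reference Gene-model tibbles.
#' @param regions Optional evaluation windows: tibble with `scaffold`,
#'   `start`, `end`.
#' @return A `prediction_eval` tibble: `level`, `tp`, `n_reference`,
#'   `n_predicted`, `sensitivity`, `precision`, `precision_defined`.
#'   [tidy()] returns it as a plain tibble; [glance()] gives the one-row
#'   exon/transcript summary with their summed accuracy.
#' @export
evaluate_predictions <- function(predicted, reference, regions = NULL) {
  pred_ex <- eval_exons(predicted, regions)
  ref_ex <- eval_exons(reference, NULL)
  exon_tp <- nrow(semi_join(pred_ex, ref_ex,
                            by = c("scaffold", "strand", "start", "end")))

  pred_tx <- eval_signatures(predicted, regions)
  ref_tx <- eval_signatures(reference, NULL)
  tx_tp <- sum(pred_tx$sig %in% ref_tx$sig)

  pred_utr <- utr_intervals(predicted, regions)
  ref_utr <- utr_intervals(reference, regions)
  utr_tp <- interval_set_overlap(pred_utr, ref_utr)
  n_ref_utr <- interval_set_size(ref_utr)
  n_pred_utr <- interval_set_size(pred_utr)

  lvl <- function(level, tp, n_ref, n_pred) {
    tibble(level = level, tp = tp, n_reference = n_ref, n_predicted = n_pred,
           sensitivity = if (n_ref > 0) tp / n_ref else 0,
           precision = if (n_pred > 0) tp / n_pred else 0,
           precision_defined = n_pred > 0)
  }
  out <- bind_rows(
    lvl("exon", exon_tp, nrow(ref_ex), nrow(pred_ex)),
    lvl("transcript", tx_tp, nrow(ref_tx), nrow(pred_tx)),
    lvl("utr_base", utr_tp, n_ref_utr, n_pred_utr)
  )
  class(out) <- c("prediction_eval", class(out))
  out
}

#' @export
tidy.prediction_eval <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "prediction_eval")
  out
}

#' @export
glance.prediction_eval <- function(x, ...) {
  g <- function(level, col) x[[col]][x$level == level]
  tibble(
    exon_sensitivity = g("exon", "sensitivity"),
    exon_precision = g("exon", "precision"),
    transcript_sensitivity = g("transcript", "sensitivity"),
    transcript_precision = g("transcript", "precision"),
    utr_base_sensitivity = g("utr_base", "sensitivity"),
    utr_base_precision = g("utr_base", "precision"),
    accuracy_sum = g("exon", "sensitivity") + g("exon", "precision") +
      g("transcript", "sensitivity") + g("transcript", "precision")
  )
}

eval_exons <- function(genes, regions) {
  ex <- genes |> distinct(.data$scaffold, .data$strand, .data$start,
                          .data$end)
  if (!is.null(regions) && nrow(ex)) {
    ex <- ex |>
      inner_join(regions |> select("scaffold", rs = "start", re = "end"),
                 by = "scaffold", relationship = "many-to-many") |>
      filter(.data$start < .data$re, .data$end > .data$rs) |>
      distinct(.data$scaffold, .data$strand, .data$start, .data$end)
  }
  ex
}

eval_signatures <- function(genes, regions) {
  if (!nrow(genes)) {
    return(tibble(transcript_id = character(), scaffold = character(),
                  strand = character(), span_start = integer(),
                  span_end = integer(), sig = character()))
  }
  sig <- genes |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    summarise(scaffold = .data$scaffold[1L], strand = .data$strand[1L],
              span_start = min(.data$start), span_end = max(.data$end),
              sig = paste0(.data$scaffold[1L], ":", .data$strand[1L], ":",
                           paste(.data$start, .data$end, sep = "-",
                                 collapse = ";")),
              .groups = "drop")
  if (!is.null(regions) && nrow(sig)) {
    sig <- sig |>
      inner_join(regions |> select("scaffold", rs = "start", re = "end"),
                 by = "scaffold", relationship = "many-to-many") |>
      filter(.data$span_start < .data$re, .data$span_end > .data$rs) |>
      distinct(.data$transcript_id, .keep_all = TRUE)
  }
  sig
}

# UTR intervals (exon minus CDS span) per scaffold/strand, clipped to
# regions; returned as a tibble scaffold, strand, start, end (merged).
utr_intervals <- function(genes, regions) {
  if (!nrow(genes)) {
    return(tibble(scaffold = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  utr <- genes |>
    mutate(cs = coalesce(.data$cds_start, .data$end),
           ce = coalesce(.data$cds_end, .data$end)) |>
    reframe(
      scaffold = rep(.data$scaffold, 2L),
      strand = rep(.data$strand, 2L),
      start = c(.data$start, pmax(.data$start, .data$ce)),
      end = c(pmin(.data$end, .data$cs), .data$end)
    ) |>
    filter(.data$start < .data$end)
  if (!is.null(regions) && nrow(utr)) {
    utr <- utr |>
      inner_join(regions |> select("scaffold", rs = "start", re = "end"),
                 by = "scaffold", relationship = "many-to-many") |>
      mutate(start = pmax(.data$start, .data$rs),
             end = pmin(.data$end, .data$re)) |>
      filter(.data$start < .data$end) |>
      select(-"rs", -"re")
  }
  utr |>
    group_by(.data$scaffold, .data$strand) |>
    reframe({
      m <- merge_runs(.data$start, .data$end)
      tibble(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]))
    })
}

interval_set_size <- function(x) {
  if (!nrow(x)) return(0L)
  sum(x$end - x$start)
}

interval_set_overlap <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0L)
  keys <- inner_join(distinct(a, .data$scaffold, .data$strand),
                     distinct(b, .data$scaffold, .data$strand),
                     by = c("scaffold", "strand"))
  tot <- 0
  for (i in seq_len(nrow(keys))) {
    aa <- a |> filter(.data$scaffold == keys$scaffold[i],
                      .data$strand == keys$strand[i])
    bb <- b |> filter(.data$scaffold == keys$scaffold[i],
                      .data$strand == keys$strand[i])
    tot <- tot + overlap_bases(aa$start, aa$end, bb$start, bb$end)
  }
  tot
}

#' Select non-redundant training and test genes
#'
#' Genes whose CDS length is not divisible by 3 are removed, then redundant
#' genes: for every pair with protein sequence identity at or above
#' `cfg$redundancy_identity` (80\%), the gene with the shorter CDS is
#' dropped (pairs processed in descending identity). The survivors are
#' randomly split into `n_train` training and `n_test` test genes; the same
#' seed always yields the same split.
#'
#' @param genes Gene-model tibble with CDS coordinates.
#' @param identities Pairwise protein identities: tibble with `id1`, `id2`
#'   (gene ids) and `identity` in `[0, 1]` (from an external all-vs-all
#'   protein alignment).
#' @param n_train,n_test Requested split sizes.
#' @param seed Integer seed for the random split.
#' @param cfg A [pipeline_config()].
#' @return A list with character vectors `train` and `test`.
#' @export
select_training_genes <- function(genes, identities, n_train, n_test, seed,
                                  cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  cds_len <- genes |>
    mutate(cs = pmax(.data$start, .data$cds_start),
           ce = pmin(.data$end, .data$cds_end)) |>
    group_by(.data$gene_id) |>
    summarise(len = sum(pmax(0L, .data$ce - .data$cs)), .groups = "drop")
  pool <- cds_len |> filter(.data$len > 0L, .data$len %% 3L == 0L)
  alive <- pool$gene_id
  len_of <- stats::setNames(pool$len, pool$gene_id)
  pairs <- identities |>
    filter(.data$identity >= cfg$redundancy_identity,
           .data$id1 %in% alive, .data$id2 %in% alive,
           .data$id1 != .data$id2) |>
    arrange(desc(.data$identity), .data$id1, .data$id2)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$id1[i]; b <- pairs$id2[i]
    if (!(a %in% alive) || !(b %in% alive)) next
    victim <- if (len_of[[a]] < len_of[[b]]) a
      else if (len_of[[b]] < len_of[[a]]) b
      else max(a, b)  # equal lengths: drop the lexicographically later id
    alive <- setdiff(alive, victim)
  }
  if (length(alive) < n_train + n_test) {
    abort(paste0("only ", length(alive), " non-redundant genes available; ",
                 n_train + n_test, " requested"))
  }
  withr::with_seed(seed, {
    picked <- sample(sort(alive), n_train + n_test)
    list(train = sort(picked[seq_len(n_train)]),
         test = sort(picked[n_train + seq_len(n_test)]))
  })
}

#' Predict 1:1 orthologs by reciprocal best hits
#'
#' Hits are filtered to e-value at most `cfg$rbh_evalue` (1e-5) and
#' alignment length at least `cfg$rbh_min_len_fraction` (50\%) of the query
#' protein length. The best hit per query is the highest bitscore (ties:
#' lower e-value, then lexicographic subject id). A pair is reported when
#' each protein is the other's best hit.
#'
#' @param hits_ab,hits_ba Hit tables (species A queried against B and vice
#'   versa): tibbles with `query`, `subject`, `evalue`, `bitscore`,
#'   `alignment_length`, `qlen`.
#' @param cfg A [pipeline_config()].
#' @return A tibble of 1:1 pairs with columns `a` (query id in `hits_ab`)
#'   and `b`, sorted by `a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  best <- function(hits) {
    hits |>
      filter(.data$evalue <= cfg$rbh_evalue,
             .data$alignment_length >=
               cfg$rbh_min_len_fraction * .data$qlen) |>
      group_by(.data$query) |>
      arrange(desc(.data$bitscore), .data$evalue, .data$subject,
              .by_group = TRUE) |>
      slice(1L) |>
      ungroup() |>
      select("query", "subject")
  }
  ab <- best(hits_ab)
  ba <- best(hits_ba)
  ab |>
    inner_join(ba, by = c(query = "subject", subject = "query")) |>
    transmute(a = .data$query, b = .data$subject) |>
    arrange(.data$a)
}

#' Genes expressed exclusively under stress conditions
#'
#' Selects genes with no expression hint coverage under the control
#' condition and at least `cfg$stress_cds_cov` (90\%) CDS coverage under at
#' least one stress condition.
#'
#' @param gene_coverage Long tibble with `gene_id`, `condition` and
#'   `coverage` (fraction of the CDS covered by expression hints, in
#'   `[0, 1]`).
#' @param cfg A [pipeline_config()].
#' @param control Name of the control condition (default `"control"`).
#' @return Sorted character vector of stress-specific gene ids.
#' @export
stress_specific_genes <- function(gene_coverage, cfg = pipeline_config(),
                                  control = "control") {
  cfg <- as_config(cfg)
  if (any(gene_coverage$coverage < 0 | gene_coverage$coverage > 1)) {
    abort("coverage fractions must lie in [0, 1]")
  }
  gene_coverage |>
    group_by(.data$gene_id) |>
    summarise(
      ctrl = max(c(0, .data$coverage[.data$condition == control])),
      stress = max(c(0, .data$coverage[.data$condition != control])),
      .groups = "drop") |>
    filter(.data$ctrl == 0, .data$stress >= cfg$stress_cds_cov) |>
    pull("gene_id") |>
    sort()
}

#' Mean alignment identity of full-length aligning reads
#'
#' Keeps the best alignment per read (largest aligned length, then highest
#' identity), requires at least `cfg$min_align_fraction` (90\%) of the read
#' length to be aligned, and returns the unweighted mean identity -- the
#' sequence accuracy estimate of the read set.
#'
#' @param alignments Alignment tibble with `read_id`, `read_length`,
#'   `aligned_bases` and `identity` (block rows are fine; read-level values
#'   are de-duplicated).
#' @param cfg A [pipeline_config()].
#' @return The mean identity (a single number).
#' @export
alignment_accuracy <- function(alignments, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  kept <- alignments |>
    distinct(.data$read_id, .data$read_length, .data$aligned_bases,
             .data$identity) |>
    group_by(.data$read_id) |>
    arrange(desc(.data$aligned_bases), desc(.data$identity),
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    filter(.data$aligned_bases / .data$read_length >=
             cfg$min_align_fraction)
  if (nrow(kept) == 0L) abort("no qualifying alignments")
  mean(kept$identity)
}
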