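#' Reduce coverage by a fraction of the local peak
#'
#' For every non-overlapping `cfg$window_size` (1,000 base) window of a
#' contiguous coverage track (windows tile from the track start; the last
#' window may be short), the local peak is the nearest-rank
#' `cfg$peak_percentile` (95th) percentile of the window's depths, and every
#' depth in the window is reduced by `cfg$peak_reduction` (10\%) of that
#' peak, clamping at zero. This removes a depth floor proportional to local
#' expression, suppressing background such as incompletely spliced mRNA
#' while leaving high-coverage exons essentially intact.
#'
#' @param coverage Coverage tibble (`scaffold`, `pos`, `depth`; see
#'   [read_wiggle()]).
#' @param cfg A [pipeline_config()].
#' @return The coverage tibble with reduced depths.
#' @export
peak_normalize_coverage <- function(coverage, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(coverage) == 0L) return(coverage)
  cov <- coverage_tracks(coverage)
  out <- cov |>
    group_by(.data$track) |>
    mutate(win = (row_number() - 1L) %/% cfg$window_size) |>
    group_by(.data$track, .data$win) |>
    mutate(depth = {
      p <- nearest_rank_percentile(.data$depth, cfg$peak_percentile)
      pmax(0, .data$depth - cfg$peak_reduction * p)
    }) |>
    ungroup() |>
    select(-"track", -"win")
  out[names(coverage)]
}

# Nearest-rank percentile: value at index ceiling(q/100 * n) of the sorted
# vector.
nearest_rank_percentile <- function(x, q) {
  sort(x)[max(1L, ceiling(q / 100 * length(x)))]
}

#' Drop weak intron hints overlapped by much stronger ones
#'
#' When two intron hints overlap and their relative multiplicity difference
#' `(mult(a) - mult(b)) / mult(a)` (a the stronger hint) exceeds
#' `cfg$intron_hint_diff` (90\%), the weaker hint is removed -- such hints
#' typically stem from rare isoforms or mis-spliced reads shadowing a real
#' intron. The rule is applied against survivors in descending-multiplicity
#' order until a fixed point is reached, so removal by an already removed
#' hint cannot occur.
#'
#' @param hints Hint tibble of `kind == "intron"` hints; `multiplicity` is
#'   the supporting read count.
#' @param cfg A [pipeline_config()].
#' @return The surviving hint rows (a subset of the input).
#' @export
filter_overlapping_intron_hints <- function(hints,
                                            cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(hints) <= 1L) return(hints)
  ord <- order(-hints$multiplicity, hints$scaffold, hints$start, hints$end)
  keep_idx <- integer()
  for (j in ord) {
    dominated <- FALSE
    for (k in keep_idx) {
      if (hints$scaffold[k] == hints$scaffold[j] &&
          hints$start[k] < hints$end[j] &&
          hints$end[k] > hints$start[j]) {
        a <- hints$multiplicity[k]; b <- hints$multiplicity[j]
        if ((a - b) / a > cfg$intron_hint_diff) {
          dominated <- TRUE
          break
        }
      }
    }
    if (!dominated) keep_idx <- c(keep_idx, j)
  }
  hints[sort(keep_idx), , drop = FALSE]
}

#' Attenuate coverage inside supported introns
#'
#' An intron qualifies for attenuation when it is at most `cfg$max_intron`
#' (50,000) bases long and shows a coverage drop of at least
#' `cfg$junction_drop` (50\%) at *both* exon-intron junctions, comparing the
#' mean depth of the `cfg$junction_flank` (10) intron-side bases against the
#' mean of the 10 exon-side bases. Every base of a qualifying intron is
#' reduced by `cfg$intron_attenuation` (50\%) of the adjacent exon coverage
#' `E` (the mean of the two exon-side means), clamping at zero. Positions
#' absent from the coverage table count as depth zero in the junction means.
#'
#' @param coverage Coverage tibble.
#' @param intron_hints Hint tibble of surviving intron hints (see
#'   [filter_overlapping_intron_hints()]).
#' @param cfg A [pipeline_config()].
#' @return The coverage tibble with attenuated intronic depths.
#' @export
attenuate_intronic_coverage <- function(coverage, intron_hints,
                                        cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(coverage) == 0L || nrow(intron_hints) == 0L) return(coverage)
  f <- cfg$junction_flank
  out <- coverage
  for (scaf in unique(intron_hints$scaffold)) {
    rows <- which(out$scaffold == scaf)
    if (!length(rows)) next
    pos <- out$pos[rows]
    hi <- max(pos) + f + 1L
    dense <- numeric(hi + 1L)  # depth at 0-based position p is dense[p + 1]
    dense[pos + 1L] <- out$depth[rows]
    dense0 <- dense  # junction statistics use the pre-attenuation snapshot,
                     # so the result is independent of intron order
    mean_at <- function(from, to) {
      # mean depth over [from, to); positions off the track count as zero
      i <- pmax(from, 0L):min(to - 1L, hi)
      tot <- if (i[1L] > i[length(i)]) 0 else sum(dense0[i + 1L])
      tot / (to - from)
    }
    introns <- intron_hints |> filter(.data$scaffold == scaf)
    for (i in seq_len(nrow(introns))) {
      h <- introns[i, ]
      if (h$end - h$start > cfg$max_intron) next
      ex_l <- mean_at(h$start - f, h$start)
      in_l <- mean_at(h$start, h$start + f)
      in_r <- mean_at(h$end - f, h$end)
      ex_r <- mean_at(h$end, h$end + f)
      drop_ok <- in_l <= (1 - cfg$junction_drop) * ex_l &&
        in_r <= (1 - cfg$junction_drop) * ex_r
      if (!drop_ok) next
      e_mean <- (ex_l + ex_r) / 2
      span <- pmax(h$start, 0L):min(h$end - 1L, hi)
      dense[span + 1L] <- pmax(0, dense[span + 1L] -
                                 cfg$intron_attenuation * e_mean)
    }
    out$depth[rows] <- dense[pos + 1L]
  }
  out
}

#' Promote well-supported introns to anchors
#'
#' Intron hints supported by at least `cfg$anchor_min_reads` (50) aligned
#' reads are duplicated as anchor hints (`source = "M"`), which the gene
#' predictor is configured to honor with an overwhelming bonus
#' (`cfg$anchor_bonus`, 1e+100). The original expression hints are
#' retained.
#'
#' @param hints Hint tibble of intron hints.
#' @param cfg A [pipeline_config()].
#' @return The input hints plus one `source = "M"` copy of each qualifying
#'   hint, in stable sort order.
#' @export
promote_intron_anchors <- function(hints, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(hints) == 0L) return(hints)
  anchors <- hints |>
    filter(.data$multiplicity >= cfg$anchor_min_reads) |>
    mutate(source = "M")
  sort_hints(bind_rows(hints, anchors))
}

#' Full mRNA-seq noise-reduction pipeline
#'
#' Applies, in order: peak normalization of the coverage, removal of
#' overshadowed intron hints, attenuation of intronic coverage, and anchor
#' promotion. The order mirrors the processing narrative of the protocol:
#' hints are cleaned before they gate the coverage attenuation.
#'
#' @param coverage Coverage tibble.
#' @param intron_hints Hint tibble of intron hints.
#' @param cfg A [pipeline_config()].
#' @return A list with elements `coverage` (filtered tibble) and `hints`
#'   (surviving intron hints plus anchors).
#' @export
reduce_expression_noise <- function(coverage, intron_hints,
                                    cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  cov <- peak_normalize_coverage(coverage, cfg)
  kept <- filter_overlapping_intron_hints(intron_hints, cfg)
  cov <- attenuate_intronic_coverage(cov, kept, cfg)
  list(coverage = cov, hints = promote_intron_anchors(kept, cfg))
}
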