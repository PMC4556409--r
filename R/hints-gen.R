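#' Convert selected isoforms to predictor hints
#'
#' Each selected isoform becomes one hint group: internal exons are emitted
#' as `exon` hints, terminal exons as `exonpart` hints (their outer
#' boundaries are median read ends, not confirmed splice sites), and introns
#' as `intronpart` hints. All hints of an isoform share a deterministic
#' group id so the predictor treats them as one transcript. `mode = "E"`
#' emits ordinary expression hints; `mode = "M"` emits anchors the predictor
#' must honor.
#'
#' @param clusters Selected clusters with derived boundaries (see
#'   [select_isoforms()] and [derive_boundaries()]).
#' @param mode Hint source: `"E"` (expression evidence) or `"M"` (anchor).
#' @param cfg A [pipeline_config()].
#' @return A hint tibble; multiplicity is the isoform's read support.
#' @export
isoform_to_hints <- function(clusters, mode = c("E", "M"),
                             cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  mode <- match.arg(mode)
  if (nrow(clusters) == 0L) return(empty_hints())
  out <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    ex <- chain_to_exons(cl$start, cl$end, cl$chain)
    n <- nrow(ex)
    grp <- hint_group_id(cl$scaffold, cl$start, cl$chain)
    kind <- if (n == 1L) "exonpart" else {
      c("exonpart", rep("exon", n - 2L), "exonpart")
    }
    h <- new_hints(cl$scaffold, kind, ex$start, ex$end, cl$strand, mode,
                   cfg$expression_priority, grp, cl$n_reads)
    if (n > 1L) {
      h <- bind_rows(h, new_hints(cl$scaffold, "intronpart",
                                  head(ex$end, -1L), tail(ex$start, -1L),
                                  cl$strand, mode, cfg$expression_priority,
                                  grp, cl$n_reads))
    }
    out[[i]] <- h
  }
  sort_hints(bind_rows(out))
}

# Deterministic group id: scaffold + start + a small chain hash.
hint_group_id <- function(scaffold, start, chain) {
  h <- sum(utf8ToInt(chain) * (seq_len(nchar(chain)) %% 97L + 1L)) %% 100000L
  sprintf("%s_%d_%05d", scaffold, start, h)
}

#' Add flanking intergenic hints around hint groups
#'
#' To prevent the predictor from appending further exons to an isoform hint
#' group, a length-one `irpart` (intergenic) hint is placed
#' `cfg$flank_distance` (50) bases away on each side of the group span:
#' upstream at `group_start - 51` and downstream at `group_end + 50`
#' (0-based). Flanks falling outside the scaffold are dropped.
#'
#' @param hints Hint tibble containing one or more groups (`group` column
#'   set).
#' @param scaffold_lengths Named integer vector or tibble
#'   (`scaffold`, `length`).
#' @param cfg A [pipeline_config()].
#' @return The input hints plus the surviving `irpart` flanks, sorted.
#' @export
add_flanking_intergenic_hints <- function(hints, scaffold_lengths,
                                          cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(hints) == 0L) return(hints)
  if (is.data.frame(scaffold_lengths)) {
    lens <- scaffold_lengths$length
    names(lens) <- scaffold_lengths$scaffold
  } else {
    lens <- scaffold_lengths
  }
  grouped <- hints |> filter(!is.na(.data$group))
  if (nrow(grouped) == 0L) return(hints)
  spans <- grouped |>
    group_by(.data$group) |>
    summarise(scaffold = .data$scaffold[1L], strand = .data$strand[1L],
              source = .data$source[1L], priority = .data$priority[1L],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  d <- cfg$flank_distance
  flanks <- bind_rows(
    spans |> mutate(pos = .data$start - d - 1L),
    spans |> mutate(pos = .data$end + d)
  )
  L <- lens[flanks$scaffold]
  if (any(is.na(L))) {
    abort(paste0("unknown scaffold length for: ",
                 flanks$scaffold[is.na(L)][1L]))
  }
  flanks <- flanks |>
    filter(.data$pos >= 0L, .data$pos < L) |>
    (\(x) new_hints(x$scaffold, "irpart", x$pos, x$pos + 1L, x$strand,
                    x$source, x$priority, x$group, 1L))()
  sort_hints(bind_rows(hints, flanks))
}

#' Convert repeat intervals to non-exonic hints
#'
#' Transposable-element intervals become `nonexonpart` hints with
#' `source = "RM"` at `cfg$repeat_priority` (6), above the expression
#' evidence priority, so repeat regions are excluded from gene models even
#' where expression hints overlap them. Intervals are emitted as-is, one
#' hint per input row, without merging.
#'
#' @param repeats Tibble of repeat intervals: `scaffold`, `start`, `end`,
#'   optional `strand`.
#' @param cfg A [pipeline_config()].
#' @return A hint tibble, one row per input interval.
#' @export
repeats_to_hints <- function(repeats, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(repeats) == 0L) return(empty_hints())
  strand <- if ("strand" %in% names(repeats)) repeats$strand else "."
  new_hints(repeats$scaffold, "nonexonpart", repeats$start, repeats$end,
            strand, "RM", cfg$repeat_priority)
}

#' Emit the extrinsic-evidence configuration fragment
#'
#' Renders the predictor weight settings as a deterministic text block:
#' the repeat (`RM`) bonus for non-exonic regions (default 1e+10, raised
#' from the predictor's 1.01), the intron malus (default 0.001, tightened
#' from 0.34), the anchor (`M`) intron bonus (default 1e+100), and the
#' priority levels for repeat and expression hints. Two calls with the same
#' configuration produce byte-identical output.
#'
#' @param cfg A [pipeline_config()].
#' @return A single character string (the config fragment).
#' @examples
#' cat(emit_extrinsic_config())
#' @export
emit_extrinsic_config <- function(cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  lines <- c(
    "[SOURCES]",
    "M RM E",
    "",
    "[GENERAL]",
    paste0("      exon        1    1        M 1 ", format(cfg$anchor_bonus),
           "  RM 1 1  E 1 1"),
    paste0("      exonpart    1    1        M 1 ", format(cfg$anchor_bonus),
           "  RM 1 1  E 1 1"),
    paste0("      intron      1    ", format(cfg$intron_malus),
           "    M 1 ", format(cfg$anchor_bonus), "  RM 1 1  E 1 1"),
    paste0("      intronpart  1    1        M 1 ", format(cfg$anchor_bonus),
           "  RM 1 1  E 1 1"),
    paste0("      nonexonpart 1    1        M 1 1  RM 1 ",
           format(cfg$repeat_bonus), "  E 1 1"),
    "      irpart      1    1        M 1 1  RM 1 1  E 1 1",
    "",
    paste0("# priority: RM=", cfg$repeat_priority, " expression=",
           cfg$expression_priority)
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}
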