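#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` rows of a GFF3 file into a tidy
#' gene-model table. GFF3 coordinates (1-based, inclusive) are converted to
#' the package-internal 0-based half-open convention at this boundary.
#'
#' @param path Path to a GFF3 file.
#'
#' @return A tibble with one row per exon and columns `gene_id`,
#'   `transcript_id`, `scaffold`, `strand`, `start`, `end`, `exon_rank`
#'   (ascending genomic order), `cds_start`, `cds_end` (`NA` for non-coding
#'   transcripts; the CDS genomic span), `evidence_fraction` (`NA` unless an
#'   `evidence_fraction` attribute is present on the mRNA row) and
#'   `attributes` (unparsed extra mRNA attributes, preserved verbatim on
#'   round trip).
#' @seealso [write_gff3_genes()] for the inverse.
#' @export
read_gff3_genes <- function(path) {
  rows <- read_gff_rows(path)
  empty <- tibble(
    gene_id = character(), transcript_id = character(),
    scaffold = character(), strand = character(),
    start = integer(), end = integer(), exon_rank = integer(),
    cds_start = integer(), cds_end = integer(),
    evidence_fraction = double(), attributes = character()
  )
  if (nrow(rows) == 0L) return(empty)
  rows <- rows |> mutate(attrs = map(.data$attributes, parse_gff_attrs))
  rows$id <- map_chr(rows$attrs, ~.x[["ID"]] %||% NA_character_)
  rows$parent <- map_chr(rows$attrs, ~.x[["Parent"]] %||% NA_character_)

  genes <- rows |> filter(.data$type == "gene")
  mrnas <- rows |> filter(.data$type %in% c("mRNA", "transcript"))
  exons <- rows |> filter(.data$type == "exon")
  cdss <- rows |> filter(.data$type == "CDS")
  for (child in list(exons, cdss)) {
    if (nrow(child) == 0L) next
    bad <- is.na(child$parent) | !(child$parent %in% mrnas$id)
    if (any(bad)) {
      abort(paste0("GFF3 parse error at line ", child$line[bad][1L],
                   ": unknown parent '",
                   child$parent[bad][1L] %||% "<missing>", "'"))
    }
  }
  if (nrow(mrnas) == 0L) return(empty)

  if (any(is.na(mrnas$id))) {
    bad <- mrnas$line[is.na(mrnas$id)][1L]
    abort(paste0("GFF3 parse error at line ", bad, ": mRNA without ID"))
  }
  orphan <- !is.na(mrnas$parent) & !(mrnas$parent %in% genes$id)
  if (any(orphan)) {
    abort(paste0("GFF3 parse error at line ", mrnas$line[orphan][1L],
                 ": unknown parent '", mrnas$parent[orphan][1L], "'"))
  }
  mrna_tbl <- mrnas |>
    transmute(
      transcript_id = .data$id,
      gene_id = coalesce(.data$parent, .data$id),
      mrna_start = .data$start, mrna_end = .data$end,
      mrna_scaffold = .data$scaffold, mrna_strand = .data$strand,
      evidence_fraction = map_dbl(.data$attrs, function(a) {
        v <- a[["evidence_fraction"]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }),
      attributes = map_chr(.data$attrs, function(a) {
        keep <- setdiff(names(a), c("ID", "Parent", "evidence_fraction"))
        if (!length(keep)) return(NA_character_)
        paste(keep, unlist(a[keep]), sep = "=", collapse = ";")
      })
    )

  ex_tbl <- exons |>
    transmute(transcript_id = .data$parent, scaffold = .data$scaffold,
              strand = .data$strand, start = .data$start, end = .data$end)
  # transcripts without explicit exon rows span a single exon
  no_exon <- setdiff(mrna_tbl$transcript_id, ex_tbl$transcript_id)
  if (length(no_exon)) {
    ex_tbl <- bind_rows(ex_tbl, mrna_tbl |>
      filter(.data$transcript_id %in% no_exon) |>
      transmute(.data$transcript_id, scaffold = .data$mrna_scaffold,
                strand = .data$mrna_strand,
                start = .data$mrna_start, end = .data$mrna_end))
  }
  cds_tbl <- cdss |>
    group_by(transcript_id = .data$parent) |>
    summarise(cds_start = min(.data$start), cds_end = max(.data$end),
              .groups = "drop")

  out <- ex_tbl |>
    arrange(.data$scaffold, .data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = row_number()) |>
    ungroup() |>
    left_join(cds_tbl, by = "transcript_id") |>
    left_join(mrna_tbl |> select("transcript_id", "gene_id",
                                 "evidence_fraction", "attributes"),
              by = "transcript_id") |>
    select("gene_id", "transcript_id", "scaffold", "strand", "start", "end",
           "exon_rank", "cds_start", "cds_end", "evidence_fraction",
           "attributes")
  check_intervals(out, "exon")
  spans <- out |> group_by(.data$transcript_id) |>
    summarise(s = min(.data$start), .groups = "drop")
  out |>
    left_join(spans, by = "transcript_id") |>
    arrange(.data$scaffold, .data$s, .data$transcript_id, .data$start) |>
    select(-"s")
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` rows with 1-based inclusive
#' coordinates, sorted by scaffold then start. CDS rows are the intersection
#' of the exons with the stored CDS genomic span. Extra mRNA attributes kept
#' in the `attributes` column are written back verbatim.
#'
#' @param genes Gene-model tibble as returned by [read_gff3_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  if (nrow(genes)) {
    check_intervals(genes, "exon")
    tx <- genes |>
      group_by(.data$gene_id, .data$transcript_id) |>
      summarise(scaffold = .data$scaffold[1L], strand = .data$strand[1L],
                start = min(.data$start), end = max(.data$end),
                cds_start = .data$cds_start[1L], cds_end = .data$cds_end[1L],
                evidence_fraction =
                  if ("evidence_fraction" %in% names(genes))
                    .data$evidence_fraction[1L] else NA_real_,
                attributes = if ("attributes" %in% names(genes))
                  .data$attributes[1L] else NA_character_,
                .groups = "drop") |>
      arrange(.data$scaffold, .data$start, .data$transcript_id)
    body <- character()
    for (i in seq_len(nrow(tx))) {
      t <- tx[i, ]
      ex <- genes |> filter(.data$transcript_id == t$transcript_id) |>
        arrange(.data$start)
      extra <- ""
      if (!is.na(t$evidence_fraction)) {
        extra <- paste0(extra, ";evidence_fraction=",
                        format(t$evidence_fraction))
      }
      if (!is.na(t$attributes) && nzchar(t$attributes)) {
        extra <- paste0(extra, ";", t$attributes)
      }
      body <- c(body,
        gff_line(t$scaffold, "gene", t$start, t$end, t$strand,
                 paste0("ID=", t$gene_id)),
        gff_line(t$scaffold, "mRNA", t$start, t$end, t$strand,
                 paste0("ID=", t$transcript_id, ";Parent=", t$gene_id, extra)),
        gff_line(ex$scaffold, "exon", ex$start, ex$end, ex$strand,
                 paste0("Parent=", t$transcript_id)))
      if (!is.na(t$cds_start)) {
        cs <- pmax(ex$start, t$cds_start); ce <- pmin(ex$end, t$cds_end)
        keep <- cs < ce
        if (any(keep)) {
          body <- c(body, gff_line(ex$scaffold[keep], "CDS", cs[keep],
                                   ce[keep], ex$strand[keep],
                                   paste0("Parent=", t$transcript_id)))
        }
      }
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read spliced alignments from GFF3
#'
#' Parses `cDNA_match`/`match_part` rows (one alignment block per row, blocks
#' of one read sharing an `ID`) into a spliced-alignment table. Read-level
#' attributes `read_length`, `aligned_bases`, `identity` and `n_hits` are
#' taken from the rows when present; `read_length` and `aligned_bases`
#' default to the summed block length, `identity` to 1 and `n_hits` to 1.
#'
#' @param path Path to a GFF3 file of spliced alignments.
#' @return A tibble with one row per aligned block: `read_id`, `scaffold`,
#'   `strand`, `start`, `end`, `block_rank`, `read_length`,
#'   `aligned_bases`, `identity`, `n_hits`.
#' @export
read_gff3_alignments <- function(path) {
  rows <- read_gff_rows(path) |>
    filter(.data$type %in% c("cDNA_match", "match", "match_part"))
  if (nrow(rows) == 0L) {
    return(tibble(read_id = character(), scaffold = character(),
                  strand = character(), start = integer(), end = integer(),
                  block_rank = integer(), read_length = integer(),
                  aligned_bases = integer(), identity = double(),
                  n_hits = integer()))
  }
  rows <- rows |> mutate(attrs = map(.data$attributes, parse_gff_attrs))
  rows$read_id <- map_chr(rows$attrs, function(a) {
    a[["ID"]] %||% a[["Parent"]] %||% NA_character_
  })
  if (any(is.na(rows$read_id))) {
    abort(paste0("GFF3 parse error at line ",
                 rows$line[is.na(rows$read_id)][1L],
                 ": alignment block without ID"))
  }
  attr_num <- function(key, default) {
    map_dbl(rows$attrs, function(a) {
      v <- a[[key]]
      if (is.null(v)) default else as.numeric(v)
    })
  }
  rows$.read_length <- attr_num("read_length", NA_real_)
  rows$.aligned <- attr_num("aligned_bases", NA_real_)
  rows$.identity <- attr_num("identity", 1)
  rows$.n_hits <- attr_num("n_hits", 1)
  out <- rows |>
    arrange(.data$scaffold, .data$read_id, .data$start) |>
    group_by(.data$read_id) |>
    mutate(
      exon_sum = sum(.data$end - .data$start),
      block_rank = row_number(),
      read_length = as.integer(coalesce(.data$.read_length[1L],
                                        .data$exon_sum[1L])),
      aligned_bases = as.integer(coalesce(.data$.aligned[1L],
                                          .data$exon_sum[1L])),
      identity = .data$.identity[1L],
      n_hits = as.integer(.data$.n_hits[1L])
    ) |>
    ungroup() |>
    select("read_id", "scaffold", "strand", "start", "end", "block_rank",
           "read_length", "aligned_bases", "identity", "n_hits")
  check_intervals(out, "alignment block")
  if (any(out$aligned_bases > out$read_length)) {
    abort("invalid alignment: aligned_bases exceeds read_length")
  }
  out
}

#' Write spliced alignments to GFF3
#'
#' One `cDNA_match` row per aligned block; blocks of a read share the read id
#' in `ID` and carry the read-level attributes.
#'
#' @inheritParams write_gff3_genes
#' @param alignments Spliced-alignment tibble as from
#'   [read_gff3_alignments()].
#' @return `path`, invisibly.
#' @export
write_gff3_alignments <- function(alignments, path) {
  lines <- "##gff-version 3"
  if (nrow(alignments)) {
    check_intervals(alignments, "alignment block")
    a <- alignments |> arrange(.data$scaffold, .data$read_id, .data$start)
    lines <- c(lines, gff_line(
      a$scaffold, "cDNA_match", a$start, a$end, a$strand,
      paste0("ID=", a$read_id,
             ";read_length=", a$read_length,
             ";aligned_bases=", a$aligned_bases,
             ";identity=", format(a$identity),
             ";n_hits=", a$n_hits)))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- shared GFF machinery ----

# Raw GFF rows with original line numbers; coordinates converted to 0-based
# half-open. Errors name the offending line.
read_gff_rows <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  raw <- raw[keep]
  if (!length(raw)) {
    return(tibble(line = integer(), scaffold = character(),
                  source = character(), type = character(),
                  start = integer(), end = integer(), score = character(),
                  strand = character(), frame = character(),
                  attributes = character()))
  }
  fields <- str_split(raw, "\t")
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    abort(paste0("GFF parse error at line ", lineno[bad], ": expected 9 ",
                 "tab-separated columns, found ", nf[bad]))
  }
  m <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(start1) | is.na(end1) | end1 < start1 | start1 < 1L
  if (any(bad)) {
    abort(paste0("GFF parse error at line ", lineno[which(bad)[1L]],
                 ": invalid coordinates '", m[which(bad)[1L], 4L], "..",
                 m[which(bad)[1L], 5L], "'"))
  }
  tibble(line = lineno, scaffold = m[, 1L], source = m[, 2L], type = m[, 3L],
         start = start1 - 1L, end = end1, score = m[, 6L],
         strand = m[, 7L], frame = m[, 8L], attributes = m[, 9L])
}

parse_gff_attrs <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  parts <- str_split(s, ";")[[1]]
  parts <- parts[nzchar(parts)]
  kv <- str_split(parts, "=", n = 2L)
  vals <- as.list(map_chr(kv, function(p) if (length(p) == 2L) p[2L] else ""))
  names(vals) <- map_chr(kv, 1L)
  vals
}

gff_line <- function(scaffold, type, start, end, strand, attrs,
                     source = "smartanno", score = ".", frame = ".") {
  paste(scaffold, source, type, start + 1L, end, score, strand, frame, attrs,
        sep = "\t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
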