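HINT_KINDS <- c("exon", "exonpart", "intron", "intronpart", "nonexonpart",
                "irpart")
HINT_SOURCES <- c("E", "M", "RM")

#' Read evidence hints from the hint-GFF dialect
#'
#' The hint dialect is ordinary GFF whose feature column holds the hint kind
#' (`exon`, `exonpart`, `intron`, `intronpart`, `nonexonpart`, `irpart`) and
#' whose attribute column carries `src` (evidence source: `E` expression,
#' `M` anchor, `RM` repeat), `pri` (priority), `grp` (hint group) and `mult`
#' (multiplicity, the number of supporting reads).
#'
#' @param path Path to a hint GFF file.
#' @return A hint tibble: `scaffold`, `kind`, `start`, `end` (0-based
#'   half-open), `strand`, `source`, `priority` (`NA` if absent), `group`
#'   (`NA` if absent) and `multiplicity` (defaults to 1).
#' @export
read_hints <- function(path) {
  rows <- read_gff_rows(path)
  if (nrow(rows) == 0L) return(empty_hints())
  bad <- !(rows$type %in% HINT_KINDS)
  if (any(bad)) {
    abort(paste0("hint parse error at line ", rows$line[bad][1L],
                 ": unknown hint kind '", rows$type[bad][1L], "'"))
  }
  attrs <- map(rows$attributes, parse_gff_attrs)
  src <- map_chr(attrs, ~.x[["src"]] %||% NA_character_)
  bad <- is.na(src) | !(src %in% HINT_SOURCES)
  if (any(bad)) {
    abort(paste0("hint parse error at line ", rows$line[bad][1L],
                 ": unknown hint source '", src[bad][1L], "'"))
  }
  mult <- map_chr(attrs, ~.x[["mult"]] %||% "1")
  out <- tibble(
    scaffold = rows$scaffold,
    kind = rows$type,
    start = rows$start,
    end = rows$end,
    strand = rows$strand,
    source = src,
    priority = map_int(attrs, function(a) {
      v <- a[["pri"]]
      if (is.null(v)) NA_integer_ else as.integer(v)
    }),
    group = map_chr(attrs, ~.x[["grp"]] %||% NA_character_),
    multiplicity = as.integer(mult)
  )
  if (any(is.na(out$multiplicity)) || any(out$multiplicity < 1L)) {
    abort("hint parse error: multiplicity must be an integer >= 1")
  }
  check_intervals(out, "hint")
  out
}

#' Write evidence hints in the hint-GFF dialect
#'
#' Hints are sorted by scaffold, start and kind before emission so that
#' output is stable under permutation of the input.
#'
#' @param hints Hint tibble as from [read_hints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hints <- function(hints, path) {
  lines <- "##gff-version 3"
  if (nrow(hints)) {
    h <- sort_hints(hints)
    check_intervals(h, "hint")
    if (any(!(h$kind %in% HINT_KINDS))) abort("unknown hint kind")
    if (any(!(h$source %in% HINT_SOURCES))) abort("unknown hint source")
    attrs <- paste0("src=", h$source)
    attrs <- ifelse(is.na(h$priority), attrs,
                    paste0(attrs, ";pri=", h$priority))
    attrs <- ifelse(is.na(h$group), attrs, paste0(attrs, ";grp=", h$group))
    attrs <- paste0(attrs, ";mult=", h$multiplicity)
    lines <- c(lines, gff_line(h$scaffold, h$kind, h$start, h$end, h$strand,
                               attrs, source = "w2h"))
  }
  writeLines(lines, path)
  invisible(path)
}

sort_hints <- function(hints) {
  arrange(hints, .data$scaffold, .data$start, .data$end,
          factor(.data$kind, levels = HINT_KINDS), .data$source)
}

empty_hints <- function() {
  tibble(scaffold = character(), kind = character(), start = integer(),
         end = integer(), strand = character(), source = character(),
         priority = integer(), group = character(), multiplicity = integer())
}

new_hints <- function(scaffold, kind, start, end, strand, source, priority,
                      group = NA_character_, multiplicity = 1L) {
  tibble(scaffold = scaffold, kind = kind, start = as.integer(start),
         end = as.integer(end), strand = strand, source = source,
         priority = as.integer(priority), group = group,
         multiplicity = as.integer(multiplicity))
}
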