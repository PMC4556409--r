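#' Pipeline configuration
#'
#' All numeric thresholds of the annotation pipeline in one audited structure.
#' Every stage takes a `pipeline_config` so that deviations from the default
#' protocol are explicit and visible in one place.
#'
#' The defaults encode the protocol the package implements:
#' \describe{
#'   \item{read prefilter}{subreads shorter than `min_subread_len` (50 bases)
#'     and reads with predicted accuracy below `min_read_quality` (0.75,
#'     i.e. an expected error rate above 25\%) are discarded.}
#'   \item{full-length alignment rule}{a read maps at full length if it aligns
#'     with at least `min_align_fraction` (90\%) of its length while missing at
#'     most `max_missing_bases` (50) bases, and maps to a single locus.}
#'   \item{scaffold borders}{genes within the first or last `border_exclusion`
#'     (5,000) bases of a scaffold are treated as potentially incomplete.}
#'   \item{coverage noise reduction}{coverage is reduced by `peak_reduction`
#'     (10\%) of the local `peak_percentile` (95th) depth in `window_size`
#'     (1,000 base) windows; overlapping intron hints whose relative
#'     multiplicity difference exceeds `intron_hint_diff` (90\%) lose the
#'     weaker hint; introns up to `max_intron` (50,000) bases showing a
#'     `junction_drop` (50\%) coverage drop across `junction_flank` (10 base)
#'     junction windows are attenuated by `intron_attenuation` (50\%) of the
#'     adjacent exon coverage.}
#'   \item{anchors and predictor weights}{introns supported by at least
#'     `anchor_min_reads` (50) reads are promoted to anchors with bonus
#'     `anchor_bonus` (1e+100); the intron malus is `intron_malus` (0.001,
#'     tightened from the predictor default of 0.34); repeat hints carry bonus
#'     `repeat_bonus` (1e+10, raised from 1.01) at priority `repeat_priority`
#'     (6), above the expression-evidence priority `expression_priority` (4).}
#'   \item{primer/poly(A) detection}{primers are matched semi-globally within
#'     the terminal `primer_window` (100) bases at identity >=
#'     `primer_identity` (0.80); a poly(A) tail is the longest terminal window
#'     of at least `polya_min_len` (20) bases with A-fraction >=
#'     `polya_min_frac` (0.90).}
#'   \item{training/orthology}{proteins at >= `redundancy_identity` (80\%)
#'     identity are redundant; reciprocal best hits require e-value <=
#'     `rbh_evalue` (1e-5) and alignment length >= `rbh_min_len_fraction`
#'     (50\%) of the query; stress-specific genes need `stress_cds_cov`
#'     (90\%) CDS coverage under stress and none under control conditions.}
#' }
#'
#' @param ... Named overrides of any default value.
#'
#' @return A named list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_align_fraction
#' pipeline_config(min_isoform_reads = 3)$min_isoform_reads
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_subread_len = 50L,
    min_read_quality = 0.75,
    min_align_fraction = 0.90,
    max_missing_bases = 50L,
    border_exclusion = 5000L,
    full_orf_utr_margin = 10L,
    min_isoform_reads = 2L,
    window_size = 1000L,
    peak_percentile = 95,
    peak_reduction = 0.10,
    intron_hint_diff = 0.90,
    max_intron = 50000L,
    junction_flank = 10L,
    junction_drop = 0.50,
    intron_attenuation = 0.50,
    anchor_min_reads = 50L,
    anchor_bonus = 1e100,
    intron_malus = 0.001,
    repeat_bonus = 1e10,
    repeat_priority = 6L,
    expression_priority = 4L,
    flank_distance = 50L,
    redundancy_identity = 0.80,
    rbh_evalue = 1e-5,
    rbh_min_len_fraction = 0.50,
    stress_cds_cov = 0.90,
    # read classification (declared here, not part of the published protocol)
    primer_window = 100L,
    primer_identity = 0.80,
    min_primer_len = 10L,
    polya_min_len = 20L,
    polya_min_frac = 0.90,
    # ORF calling
    min_orf_codons = 100L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown pipeline_config field(s): ",
                   paste(bad, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  fracs <- c("min_read_quality", "min_align_fraction", "peak_reduction",
             "intron_hint_diff", "junction_drop", "intron_attenuation",
             "redundancy_identity", "rbh_min_len_fraction", "stress_cds_cov",
             "primer_identity", "polya_min_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      abort(paste0("pipeline_config$", f, " must be a fraction in [0, 1]"))
    }
  }
  lens <- c("min_subread_len", "max_missing_bases", "border_exclusion",
            "full_orf_utr_margin", "min_isoform_reads", "window_size",
            "max_intron", "junction_flank", "anchor_min_reads",
            "flank_distance", "primer_window", "min_primer_len",
            "polya_min_len", "min_orf_codons")
  for (f in lens) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v != round(v)) {
      abort(paste0("pipeline_config$", f, " must be a positive integer"))
    }
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  w <- max(nchar(names(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-*s %s\n", w, nm, format(x[[nm]])))
  }
  invisible(x)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(pipeline_config())
  if (!inherits(cfg, "pipeline_config")) {
    abort("`cfg` must be created by pipeline_config()")
  }
  cfg
}
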