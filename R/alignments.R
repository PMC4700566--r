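#' Alignment filter profile
#'
#' Thresholds for retaining tabular alignment hits of 69-bp marker sequences
#' (or gene models) against reference genomes. Two presets are provided:
#' `"ancestral"` for assigning loci to ancestral karyotype blocks
#' (E-value <= 1e-6 and match length over 40 bp, strict) and `"genome"` for
#' whole-genome comparison and genome-specificity calls (E-value <= 1e-20 and
#' match length >= 60 bp, inclusive).
#'
#' @param preset `"ancestral"` or `"genome"`.
#' @param max_e maximum E-value (inclusive).
#' @param min_len match-length threshold in bp.
#' @param len_strict `TRUE` for `length > min_len`, `FALSE` for
#'   `length >= min_len`.
#' @return object of class `alignment_filter_profile`.
#' @export
alignment_filter_profile <- function(preset = c("ancestral", "genome"),
                                     max_e = NULL, min_len = NULL,
                                     len_strict = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    ancestral = list(max_e = 1e-6, min_len = 40, len_strict = TRUE),
    genome = list(max_e = 1e-20, min_len = 60, len_strict = FALSE))
  structure(
    list(preset = preset,
         max_e = if (is.null(max_e)) def$max_e else max_e,
         min_len = if (is.null(min_len)) def$min_len else min_len,
         len_strict = if (is.null(len_strict)) def$len_strict else len_strict),
    class = "alignment_filter_profile")
}

#' Read 12-column tabular alignments
#'
#' Parses a BLAST `-outfmt 6` compatible TSV with the standard columns
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore. Subject coordinates are normalized so that
#' `subject_start <= subject_end` with the strand recorded separately.
#' Malformed rows (wrong field count or non-numeric fields) are skipped with
#' a warning that reports how many were dropped.
#'
#' @param path file path.
#' @param genome_map optional data frame with columns `sseqid` and `genome`
#'   (or a named character vector) mapping subject sequence ids to genome
#'   labels (e.g. `"Ar"`, `"An"`, `"At"`); adds a `subject_genome` column.
#' @return data frame of alignment records with normalized coordinates.
#' @export
read_blast_tab <- function(path, genome_map = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 12L
  mat <- do.call(rbind, fields[ok])
  if (is.null(mat)) mat <- matrix(character(), 0L, 12L)
  num <- suppressWarnings(apply(mat[, 3:12, drop = FALSE], 2L, as.numeric))
  if (nrow(mat) == 1L) num <- matrix(num, 1L)
  good <- if (nrow(mat)) rowSums(is.na(num)) == 0L else logical()
  bad <- sum(!ok) + sum(!good)
  if (bad > 0) warning(bad, " malformed alignment row(s) skipped")
  d <- data.frame(qseqid = mat[good, 1L], sseqid = mat[good, 2L],
                  num[good, , drop = FALSE], stringsAsFactors = FALSE)
  names(d) <- cols
  d$strand <- ifelse(d$sstart <= d$send, "+", "-")
  d$subject_start <- pmin(d$sstart, d$send)
  d$subject_end <- pmax(d$sstart, d$send)
  if (!is.null(genome_map)) {
    if (is.data.frame(genome_map))
      genome_map <- stats::setNames(genome_map$genome, genome_map$sseqid)
    d$subject_genome <- unname(genome_map[d$sseqid])
  }
  d
}

#' Filter alignment records
#'
#' Keeps records with `evalue <= max_e` and match length above (strict) or at
#' least (inclusive) the profile's length threshold. Record order is
#' preserved; filtering never adds records and is idempotent.
#'
#' @param records alignment data frame with numeric `evalue` and `length`.
#' @param profile an [alignment_filter_profile()].
#' @return the retained subset, in input order.
#' @export
#' @examples
#' r <- data.frame(evalue = c(1e-7, 1e-6), length = c(45, 40))
#' nrow(filter_alignments(r, alignment_filter_profile("ancestral")))  # 1
filter_alignments <- function(records,
                              profile = alignment_filter_profile("ancestral")) {
  stopifnot(is.data.frame(records),
            inherits(profile, "alignment_filter_profile"))
  if (nrow(records) == 0L) return(records)
  len_ok <- if (profile$len_strict) records$length > profile$min_len
            else records$length >= profile$min_len
  keep <- records$evalue <= profile$max_e & len_ok
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Read ancestral-block definitions
#'
#' Reads a BED-like TSV (`chrom`, `start`, `end`, `block`) of ancestral
#' karyotype block intervals on a reference genome. On disk the intervals are
#' 0-based half-open (BED convention); they are converted to the internal
#' 1-based inclusive convention. The 24 Brassicaceae block labels are A-X;
#' subsets are allowed.
#'
#' @param path file path.
#' @return data frame `chrom`, `start`, `end` (1-based inclusive), `block`.
#' @export
read_block_defs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "block")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("block file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$end <= d$start)) stop("empty or inverted block interval")
  data.frame(chrom = as.character(d$chrom), start = as.integer(d$start) + 1L,
             end = as.integer(d$end), block = as.character(d$block))
}
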