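#' Segregation-distortion test for an F2 marker
#'
#' Pearson chi-square test of observed genotype-class counts against the
#' Mendelian F2 expectation: 3:1 (present:absent) for a dominant
#' presence/absence marker, 1:2:1 (AA:AB:BB) for a codominant SNP.
#'
#' @param observed integer vector of class counts: length 2 (present, absent)
#'   for dominant markers, length 3 (AA, AB, BB) for codominant markers.
#' @param marker_type `"dominant_presence_absence"` or `"codominant_snp"`.
#' @return list with `chi2`, `df`, `p`.
#' @export
#' @examples
#' distortion_test(c(75, 25), "dominant_presence_absence")  # chi2 = 0
#' distortion_test(c(50, 50), "dominant_presence_absence")  # chi2 = 33.33
distortion_test <- function(observed,
                            marker_type = c("dominant_presence_absence",
                                            "codominant_snp")) {
  marker_type <- match.arg(marker_type)
  expected_ratio <- switch(marker_type,
    dominant_presence_absence = c(3, 1) / 4,
    codominant_snp = c(1, 2, 1) / 4)
  if (length(observed) != length(expected_ratio))
    stop("expected ", length(expected_ratio), " class counts for ", marker_type)
  if (any(observed < 0) || sum(observed) == 0)
    stop("class counts must be nonnegative with positive total")
  ht <- suppressWarnings(stats::chisq.test(observed, p = expected_ratio))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Scan a genotype matrix for distorted markers
#'
#' Runs [distortion_test()] on every marker and flags those distorted at
#' level `alpha`. No multiple-testing correction is applied. Distorted
#' markers are flagged rather than removed; set `drop = TRUE` to discard
#' them, mirroring the practice of excluding distorted markers before final
#' map construction.
#'
#' @param calls genotype matrix, rows = markers; codominant codes
#'   `"A"`, `"H"`, `"B"`, dominant codes `"1"`, `"0"`; `NA` missing.
#' @param marker_type character vector (recycled) of marker types.
#' @param alpha significance level for the distortion flag.
#' @param drop when `TRUE` return only undistorted markers' rows.
#' @return data frame `marker_id`, `chi2`, `df`, `p`, `distorted`.
#' @export
distortion_scan <- function(calls, marker_type = "codominant_snp",
                            alpha = 0.05, drop = FALSE) {
  ids <- rownames(calls)
  if (is.null(ids)) ids <- paste0("M", seq_len(nrow(calls)))
  marker_type <- rep_len(marker_type, nrow(calls))
  res <- lapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    counts <- if (marker_type[i] == "codominant_snp")
      c(sum(x == "A", na.rm = TRUE), sum(x == "H", na.rm = TRUE),
        sum(x == "B", na.rm = TRUE))
    else c(sum(x == "1", na.rm = TRUE), sum(x == "0", na.rm = TRUE))
    distortion_test(counts, marker_type[i])
  })
  out <- data.frame(marker_id = ids,
                    chi2 = vapply(res, `[[`, numeric(1), "chi2"),
                    df = vapply(res, `[[`, numeric(1), "df"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  out$distorted <- out$p < alpha
  if (drop) out[!out$distorted, , drop = FALSE] else out
}

#' Validate a genetic map table
#'
#' A genetic map is a data frame of loci with columns `locus_id`, `lg`
#' (linkage-group id such as `"A01"` or `"B03"`), `position_cm`, and
#' `n_markers` (markers collapsed into the locus; 1 for single-marker loci).
#' Positions must be non-decreasing within each linkage group and no locus
#' id may repeat.
#'
#' @param map genetic-map data frame.
#' @return `map`, invisibly, after validation.
#' @export
validate_genetic_map <- function(map) {
  need <- c("locus_id", "lg", "position_cm")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("map missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(map$locus_id)) stop("duplicated locus ids")
  if (any(map$position_cm < 0)) stop("negative cM position")
  bad <- vapply(split(map$position_cm, map$lg),
                function(p) is.unsorted(p), logical(1))
  if (any(bad))
    stop("cM positions not non-decreasing in: ",
         paste(names(bad)[bad], collapse = ", "))
  invisible(map)
}

#' Summarize a genetic map per linkage group
#'
#' Per linkage group: counts of single-marker loci and bin loci, total loci,
#' total mapped markers, and coverage (max cM minus min cM; 0 for a single
#' locus).
#'
#' @param map genetic-map data frame (see [validate_genetic_map()]); a missing
#'   `n_markers` column is taken as all-1.
#' @return data frame with one row per linkage group, in sorted lg order,
#'   columns `lg`, `single_marker_loci`, `bin_loci`, `total_loci`,
#'   `total_markers`, `coverage_cm`.
#' @seealso [map_table_totals()] for subgenome subtotals, grand totals and
#'   per-LG means.
#' @export
summarize_map <- function(map) {
  validate_genetic_map(map)
  if (!"n_markers" %in% names(map)) map$n_markers <- 1L
  out <- do.call(rbind, lapply(split(map, map$lg), function(d) {
    data.frame(lg = d$lg[1L],
               single_marker_loci = sum(d$n_markers == 1L),
               bin_loci = sum(d$n_markers >= 2L),
               total_loci = nrow(d),
               total_markers = sum(d$n_markers),
               coverage_cm = max(d$position_cm) - min(d$position_cm))
  }))
  rownames(out) <- NULL
  out[order(out$lg), , drop = FALSE]
}

#' Subtotals, grand totals and means for a per-linkage-group summary
#'
#' Appends to a per-LG summary table (as produced by [summarize_map()], or
#' read from a published map characteristics table) a subtotal row per
#' subgenome (linkage groups prefixed "A" and "B"), a grand-total row, and a
#' per-LG mean row (grand totals divided by the number of linkage groups,
#' rounded to `digits`).
#'
#' @param per_lg per-linkage-group summary data frame: column `lg` plus
#'   numeric columns.
#' @param digits decimal places for the mean row.
#' @return data frame: the input rows followed by rows labelled
#'   `"Subtotal A"`, `"Subtotal B"` (when present), `"Total"` and `"Mean"`.
#' @export
map_table_totals <- function(per_lg, digits = 1) {
  stopifnot(is.data.frame(per_lg), "lg" %in% names(per_lg))
  num <- names(per_lg)[vapply(per_lg, is.numeric, logical(1))]
  sum_row <- function(rows, label) {
    r <- per_lg[1, , drop = FALSE]
    r$lg <- label
    for (cn in num) r[[cn]] <- sum(per_lg[rows, cn])
    r
  }
  out <- per_lg
  for (sg in c("A", "B")) {
    rows <- startsWith(per_lg$lg, sg)
    if (any(rows)) out <- rbind(out, sum_row(rows, paste("Subtotal", sg)))
  }
  total <- sum_row(rep(TRUE, nrow(per_lg)), "Total")
  mean_row <- total
  mean_row$lg <- "Mean"
  for (cn in num) mean_row[[cn]] <- round(total[[cn]] / nrow(per_lg), digits)
  out <- rbind(out, total, mean_row)
  rownames(out) <- NULL
  out
}

#' Map resolution model from population size
#'
#' In an F2 population of n individuals the shortest resolvable genetic
#' distance under the one-centiMorgan criterion is 100/n cM; an interval
#' between that minimum and twice the minimum is treated as a "small"
#' segment. The optional physical scale converts map length to an
#' approximate Mb-per-cM rate.
#'
#' @param pop_size F2 population size (>= 2).
#' @param genome_size_mb optional genome (or subgenome) size in Mb.
#' @param map_length_cm optional total map length in cM for the same genome.
#' @return object of class `resolution_model`: `population_size`, `min_cm`
#'   (exact), `min_cm_reported` (rounded to 1 decimal), `small_max_cm`
#'   (= 2 x exact minimum), and `mb_per_cm` when the physical scale is given.
#' @export
#' @examples
#' resolution_model(168)$min_cm_reported  # 0.6
resolution_model <- function(pop_size, genome_size_mb = NA_real_,
                             map_length_cm = NA_real_) {
  if (!is.numeric(pop_size) || pop_size < 2)
    stop("pop_size must be an integer >= 2")
  if (!is.na(map_length_cm) && map_length_cm <= 0)
    stop("map_length_cm must be positive")
  min_cm <- 100 / pop_size
  structure(
    list(population_size = as.integer(pop_size),
         min_cm = min_cm,
         min_cm_reported = round(min_cm, 1),
         small_max_cm = 2 * min_cm,
         genome_size_mb = genome_size_mb,
         map_length_cm = map_length_cm,
         mb_per_cm = if (!is.na(genome_size_mb) && !is.na(map_length_cm))
           genome_size_mb / map_length_cm else NA_real_),
    class = "resolution_model")
}

#' @export
print.resolution_model <- function(x, ...) {
  cat(sprintf("Resolution model: n = %d, min distance %.1f cM (small <= %.1f cM)\n",
              x$population_size, x$min_cm_reported, x$small_max_cm))
  if (!is.na(x$mb_per_cm))
    cat(sprintf("  physical scale: %.3f Mb/cM\n", x$mb_per_cm))
  invisible(x)
}

#' Read a genetic map TSV
#'
#' Expects tab-separated columns `marker_id` (or `locus_id`), `lg`, `cM`.
#'
#' @param path file path.
#' @return data frame `locus_id`, `lg`, `position_cm`.
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  id_col <- intersect(c("locus_id", "marker_id", "marker"), names(d))[1]
  cm_col <- intersect(c("cM", "cm", "position_cm"), names(d))[1]
  if (is.na(id_col) || is.na(cm_col) || !"lg" %in% names(d))
    stop("map file needs marker/locus id, lg and cM columns")
  data.frame(locus_id = as.character(d[[id_col]]), lg = as.character(d$lg),
             position_cm = as.numeric(d[[cm_col]]))
}

#' Read a marker genotype TSV
#'
#' Rows are markers; the first columns are `id` and `type`
#' (`dominant_presence_absence` or `codominant_snp`), followed by one column
#' per individual. Codes are `1`/`0`/`-` for dominant markers and
#' `A`/`H`/`B`/`-` for codominant markers; `-` becomes `NA`.
#'
#' @param path file path.
#' @return list with `info` (data frame `id`, `type`) and `calls` (character
#'   matrix, markers x individuals).
#' @export
read_genotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (!all(c("id", "type") %in% names(d)))
    stop("genotype file needs 'id' and 'type' columns")
  calls <- as.matrix(d[, setdiff(names(d), c("id", "type")), drop = FALSE])
  calls[calls == "-"] <- NA_character_
  rownames(calls) <- d$id
  list(info = data.frame(id = d$id, type = d$type), calls = calls)
}

#' Write a marker genotype TSV
#'
#' Inverse of [read_genotypes()]; missing calls are written as `-`.
#'
#' @param info data frame with `id` and `type`.
#' @param calls character matrix, markers x individuals.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(info, calls, path) {
  x <- calls
  x[is.na(x)] <- "-"
  d <- cbind(info, as.data.frame(x, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
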