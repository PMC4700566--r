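#' Classify markers into co-segregation bins
#'
#' In an F2 population of limited size, markers separated by no observed
#' recombination map to the same genetic position ("bin locus"). Two markers
#' are pairwise compatible when there is no individual at which both calls
#' are non-missing and disagree; bins are the connected components of the
#' pairwise-compatibility graph (missing-tolerant transitive closure).
#' Bin identifiers are deterministic: the lexicographically smallest member
#' id names the bin. A marker with all calls missing carries no segregation
#' information; it becomes a singleton bin and is flagged.
#'
#' @param calls matrix of genotype calls, rows = markers (rownames are marker
#'   ids), columns = individuals. Any atomic type; `NA` marks missing.
#' @return data frame with one row per marker: `marker_id`, `bin_id`,
#'   `n_members` (size of the marker's bin) and `all_missing`.
#' @seealso [bin_loci()] to pick representatives per bin.
#' @export
#' @examples
#' g <- rbind(m2 = c("A", "H", NA), m1 = c("A", "H", "B"),
#'            m3 = c("B", "H", "A"))
#' classify_bins(g)   # m1 and m2 share a bin named "m1"
classify_bins <- function(calls) {
  if (is.null(dim(calls))) stop("'calls' must be a matrix")
  m <- nrow(calls)
  if (m == 0L)
    return(data.frame(marker_id = character(), bin_id = character(),
                      n_members = integer(), all_missing = logical()))
  ids <- rownames(calls)
  if (is.null(ids)) ids <- paste0("M", seq_len(m))
  if (anyDuplicated(ids)) stop("duplicated marker ids")

  all_missing <- apply(calls, 1L, function(x) all(is.na(x)))

  # union-find over pairwise-compatible markers
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      if (all_missing[i]) next
      xi <- calls[i, ]
      for (j in (i + 1L):m) {
        if (all_missing[j]) next
        xj <- calls[j, ]
        ok <- !is.na(xi) & !is.na(xj)
        if (!any(xi[ok] != xj[ok])) {
          # no informative disagreement: compatible, union
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  bin_id <- vapply(split(ids, comp), function(members) min(members), character(1))
  bin_of <- bin_id[as.character(comp)]
  sizes <- table(bin_of)
  data.frame(marker_id = ids, bin_id = unname(bin_of),
             n_members = as.integer(sizes[bin_of]),
             all_missing = all_missing, row.names = NULL)
}

#' Bin loci with representative markers
#'
#' Collapses a bin partition to one row per bin locus and selects the
#' representative marker per bin: the member with the smallest missing-data
#' fraction, ties broken lexicographically by marker id. A bin with two or
#' more members is a "bin locus"; a bin of one is a single-marker locus.
#'
#' @param bins output of [classify_bins()].
#' @param calls the genotype matrix the bins were derived from (used to count
#'   missing calls per marker).
#' @return data frame with `bin_id`, `representative_id`, `n_members`,
#'   `is_bin_locus`.
#' @export
bin_loci <- function(bins, calls) {
  stopifnot(is.data.frame(bins), all(bins$marker_id %in% rownames(calls)))
  miss <- rowMeans(is.na(calls[bins$marker_id, , drop = FALSE]))
  out <- do.call(rbind, lapply(split(seq_len(nrow(bins)), bins$bin_id), function(ix) {
    ids <- bins$marker_id[ix]
    o <- order(miss[ix], ids)
    data.frame(bin_id = bins$bin_id[ix[1L]], representative_id = ids[o[1L]],
               n_members = length(ids), is_bin_locus = length(ids) >= 2L)
  }))
  rownames(out) <- NULL
  out[order(out$bin_id), , drop = FALSE]
}
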