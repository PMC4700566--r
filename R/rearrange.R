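#' Detect inversion events between two coordinate systems
#'
#' Anchors shared between system A (a genetic map in cM, or a genome in bp)
#' and system B (a genome in bp) on one homologous chromosome pair are sorted
#' by their A coordinate; anchors co-located in A (the same bin locus) share
#' a rank. Each anchor group is ranked by its B coordinate, and every
#' maximal, contiguous, strictly decreasing rank run of two or more groups is
#' a candidate inversion. In genetic units a candidate is a valid event only
#' when its A-span exceeds the map's resolving power (`resolution$min_cm`,
#' e.g. 0.6 cM for an F2 of 168); events spanning at most twice that distance
#' (1.2 cM) are "small", larger ones "large". In physical units any reversed
#' run is an event and the 1 Mb span separates small from large. A decreasing
#' run covering every anchor on the chromosome is a whole-chromosome
#' orientation flip, reported via the `"orientation_flip"` attribute rather
#' than as an inversion.
#'
#' @param anchors data frame with `id`, `chrom_a`, `coord_a`, `chrom_b`,
#'   `coord_b`; one chromosome pair per call.
#' @param resolution a [resolution_model()] (genetic units).
#' @param unit `"genetic"` (coord_a in cM) or `"physical"` (coord_a in bp).
#' @param small_max_mb small/large span boundary for physical units, in Mb.
#' @param comparison label stored with each event (e.g. `"Aj-Ar"`).
#' @return data frame of events: `comparison`, `chrom`, `start_a`, `end_a`,
#'   `span_a`, `n_anchors`, `size_class`, `anchor_ids`
#'   (comma-separated). Attribute `orientation_flip` is `TRUE` when the whole
#'   chromosome is reversed.
#' @export
detect_inversions <- function(anchors, resolution = NULL,
                              unit = c("genetic", "physical"),
                              small_max_mb = 1, comparison = "A-B") {
  unit <- match.arg(unit)
  empty <- data.frame(comparison = character(), chrom = character(),
                      start_a = numeric(), end_a = numeric(),
                      span_a = numeric(), n_anchors = integer(),
                      size_class = character(), anchor_ids = character())
  attr(empty, "orientation_flip") <- FALSE
  if (nrow(anchors) < 2L) return(empty)
  if (length(unique(anchors$chrom_a)) > 1L ||
      length(unique(anchors$chrom_b)) > 1L)
    stop("detect_inversions expects a single chromosome pair per call")
  if (unit == "genetic" && is.null(resolution))
    stop("genetic units require a resolution_model")

  a <- anchors[order(anchors$coord_a), , drop = FALSE]
  # co-located anchors (same bin) share a rank: group by coord_a
  grp <- match(a$coord_a, unique(a$coord_a))
  gb <- vapply(split(a$coord_b, grp), stats::median, numeric(1))
  rk <- match(gb, sort(unique(gb)))  # dense rank in coord_b order
  ng <- length(rk)
  if (ng < 2L) return(empty)

  # maximal strictly decreasing runs of rank, length >= 2
  runs <- list()
  s <- 1L
  for (k in 2L:ng) {
    if (rk[k] >= rk[k - 1L]) {
      if (k - 1L > s) runs[[length(runs) + 1L]] <- c(s, k - 1L)
      s <- k
    }
  }
  if (ng > s) runs[[length(runs) + 1L]] <- c(s, ng)

  flip <- length(runs) == 1L && runs[[1L]][1L] == 1L && runs[[1L]][2L] == ng
  if (flip) runs <- list()

  out <- list()
  for (r in runs) {
    members <- which(grp >= r[1L] & grp <= r[2L])
    span <- max(a$coord_a[members]) - min(a$coord_a[members])
    if (unit == "genetic") {
      if (span <= resolution$min_cm) next  # within mapping-error distance
      size <- if (span <= resolution$small_max_cm) "small" else "large"
    } else {
      if (span <= 0) next
      size <- if (span <= small_max_mb * 1e6) "small" else "large"
    }
    out[[length(out) + 1L]] <- data.frame(
      comparison = comparison, chrom = a$chrom_a[1L],
      start_a = min(a$coord_a[members]), end_a = max(a$coord_a[members]),
      span_a = span, n_anchors = length(members), size_class = size,
      anchor_ids = paste(a$id[members], collapse = ","))
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "orientation_flip") <- flip
  res
}

#' Detect translocations between two genome assemblies
#'
#' Along each source chromosome, gene anchors are expected to align to one
#' resident partner chromosome (the modal target along the source); a
#' segment of at least `min_run` successive adjacent anchors aligning to a
#' different chromosome is a translocation event ("more than four successive
#' adjacent genes" read strictly gives the default of 5).
#'
#' @param anchors data frame with `id`, `chrom_a`, `coord_a`, `chrom_b`.
#' @param min_run minimum number of successive discordant anchors.
#' @param comparison label stored with each event.
#' @return data frame of events: `comparison`, `source_chrom`,
#'   `target_chrom`, `direction` (`"a_to_b"`), `n_anchors`, `anchor_ids`.
#' @export
detect_translocations_genome_pair <- function(anchors, min_run = 5,
                                              comparison = "A-B") {
  empty <- data.frame(comparison = character(), source_chrom = character(),
                      target_chrom = character(), direction = character(),
                      n_anchors = integer(), anchor_ids = character())
  if (nrow(anchors) == 0L) return(empty)
  out <- list()
  for (ch in unique(anchors$chrom_a)) {
    d <- anchors[anchors$chrom_a == ch, , drop = FALSE]
    d <- d[order(d$coord_a), , drop = FALSE]
    r <- rle(d$chrom_b)
    if (length(r$values) < 2L) next  # uniform chromosome: nothing discordant
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    # the resident partner chromosome: the modal chrom_b along this source
    # chromosome; runs matching it are the concordant background
    resident <- names(sort(table(d$chrom_b), decreasing = TRUE))[1L]
    for (j in seq_along(r$values)) {
      if (r$lengths[j] < min_run) next
      if (r$values[j] == resident) next
      out[[length(out) + 1L]] <- data.frame(
        comparison = comparison, source_chrom = ch,
        target_chrom = r$values[j], direction = "a_to_b",
        n_anchors = r$lengths[j],
        anchor_ids = paste(d$id[starts[j]:stops[j]], collapse = ","))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  res
}

#' Candidate translocations from a genetic map
#'
#' Markers of one locus, or of two adjacent loci, are expected to align to
#' one target chromosome. When members hit two or more distinct target
#' chromosomes - each with a unique, 100-percent-identity alignment - the
#' locus (or adjacent pair) is a candidate translocation between the mapped
#' genome and the target genome. Candidates carry `confirmed = FALSE` until
#' [confirm_by_perturbation()].
#'
#' @param map genetic-map data frame (`locus_id`, `lg`, `position_cm`).
#' @param hits data frame with `marker_id`, `locus_id`, `target_chrom`,
#'   `pident`, `unique_b` (logical). Hits are pre-filtered with the
#'   `"genome"` profile.
#' @param identity_tol tolerance around 100 percent identity.
#' @param comparison label stored with each candidate.
#' @return data frame of candidates: `comparison`, `lg`, `locus_ids`
#'   (comma-separated; one or two loci), `target_chroms` (comma-separated,
#'   sorted), `n_markers`, `confirmed`.
#' @export
detect_translocations_map <- function(map, hits, identity_tol = 1e-9,
                                      comparison = "Aj-Ar") {
  stopifnot(all(c("marker_id", "locus_id", "target_chrom", "pident",
                  "unique_b") %in% names(hits)))
  h <- hits[hits$unique_b & hits$pident >= 100 - identity_tol, , drop = FALSE]
  empty <- data.frame(comparison = character(), lg = character(),
                      locus_ids = character(), target_chroms = character(),
                      n_markers = integer(), confirmed = logical())
  if (nrow(h) == 0L) return(empty)
  chroms_of <- function(lids) {
    hh <- h[h$locus_id %in% lids, , drop = FALSE]
    list(chroms = sort(unique(hh$target_chrom)), n = nrow(hh))
  }
  out <- list()
  for (g in unique(map$lg)) {
    d <- map[map$lg == g, , drop = FALSE]
    d <- d[order(d$position_cm), , drop = FALSE]
    single_hit <- logical(nrow(d))
    for (k in seq_len(nrow(d))) {
      cc <- chroms_of(d$locus_id[k])
      single_hit[k] <- length(cc$chroms) >= 1L
      if (length(cc$chroms) >= 2L)
        out[[length(out) + 1L]] <- data.frame(
          comparison = comparison, lg = g, locus_ids = d$locus_id[k],
          target_chroms = paste(cc$chroms, collapse = ","),
          n_markers = cc$n, confirmed = FALSE)
    }
    if (nrow(d) >= 2L) for (k in seq_len(nrow(d) - 1L)) {
      pair <- d$locus_id[k:(k + 1L)]
      c1 <- chroms_of(pair[1L]); c2 <- chroms_of(pair[2L])
      # pair candidate only when neither locus qualifies alone and the two
      # loci disagree on the target chromosome
      if (length(c1$chroms) == 1L && length(c2$chroms) == 1L &&
          c1$chroms != c2$chroms)
        out[[length(out) + 1L]] <- data.frame(
          comparison = comparison, lg = g,
          locus_ids = paste(pair, collapse = ","),
          target_chroms = paste(sort(c(c1$chroms, c2$chroms)), collapse = ","),
          n_markers = c1$n + c2$n, confirmed = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  res
}

#' Confirm a candidate translocation by neighbour perturbation
#'
#' The stability of a map-based candidate translocation is checked by
#' randomly reordering the loci within a window around the candidate,
#' re-running the detection, and requiring the candidate (same linkage group
#' and target chromosome set) to recur in every replicate. With
#' `n_reps = 0` the candidate is vacuously confirmed and flagged
#' `"unperturbed"`.
#'
#' @param map genetic-map data frame.
#' @param hits hit table as in [detect_translocations_map()].
#' @param candidate one row of the candidate table.
#' @param window loci on each side of the candidate to shuffle.
#' @param n_reps number of perturbation replicates.
#' @param seed RNG seed.
#' @param identity_tol,comparison passed through to the detector.
#' @return logical scalar; attribute `flag` is `"unperturbed"` when
#'   `n_reps = 0`.
#' @export
confirm_by_perturbation <- function(map, hits, candidate, window = 2,
                                    n_reps = 20, seed = 1,
                                    identity_tol = 1e-9,
                                    comparison = candidate$comparison) {
  if (n_reps == 0) {
    out <- TRUE
    attr(out, "flag") <- "unperturbed"
    return(out)
  }
  cand_loci <- strsplit(candidate$locus_ids, ",")[[1L]]
  g <- candidate$lg
  d <- map[map$lg == g, , drop = FALSE]
  d <- d[order(d$position_cm), , drop = FALSE]
  pos <- which(d$locus_id %in% cand_loci)
  lo <- max(1L, min(pos) - window)
  hi <- min(nrow(d), max(pos) + window)
  recurs <- with_seed(seed, vapply(seq_len(n_reps), function(rep) {
    perm <- seq_len(nrow(d))
    perm[lo:hi] <- sample(perm[lo:hi])
    d2 <- d[perm, , drop = FALSE]
    d2$position_cm <- sort(d$position_cm)  # loci keep the map's positions
    ev <- detect_translocations_map(d2, hits, identity_tol = identity_tol,
                                    comparison = comparison)
    any(ev$lg == g & ev$target_chroms == candidate$target_chroms)
  }, logical(1)))
  all(recurs)
}

#' Summarize rearrangement events per chromosome and comparison
#'
#' Builds a per-chromosome matrix of event counts across subgenome
#' comparisons: inversion counts formatted `"total(small)"` per comparison,
#' translocation counts per directional comparison, and a totals row equal to
#' the column sums.
#'
#' @param inversions inversion events (columns `comparison`, `chrom`,
#'   `size_class`), e.g. from [detect_inversions()].
#' @param translocations translocation events (columns `comparison`,
#'   `source_chrom`), e.g. from the translocation detectors.
#' @param chromosomes chromosome row order; defaults to those observed.
#' @return list with `table` (formatted data frame including the totals row)
#'   and `counts` (numeric per-chromosome data frame, no totals).
#' @export
summarize_rearrangements <- function(inversions, translocations = NULL,
                                     chromosomes = NULL) {
  inv_comp <- unique(inversions$comparison)
  tr_comp <- if (!is.null(translocations)) unique(translocations$comparison)
             else character()
  if (is.null(chromosomes))
    chromosomes <- sort(unique(c(inversions$chrom,
                                 translocations$source_chrom)))
  counts <- data.frame(chrom = chromosomes)
  for (cc in inv_comp) {
    tot <- sml <- integer(length(chromosomes))
    for (i in seq_along(chromosomes)) {
      e <- inversions[inversions$comparison == cc &
                      inversions$chrom == chromosomes[i], , drop = FALSE]
      tot[i] <- nrow(e)
      sml[i] <- sum(e$size_class == "small")
    }
    counts[[paste0("inv_total_", cc)]] <- tot
    counts[[paste0("inv_small_", cc)]] <- sml
  }
  for (cc in tr_comp) {
    counts[[paste0("trans_", cc)]] <- vapply(chromosomes, function(ch)
      sum(translocations$comparison == cc &
          translocations$source_chrom == ch), integer(1))
  }
  fmt <- rearrangement_totals(counts)
  list(table = fmt$table, counts = counts,
       large_inversion_total = fmt$large_inversion_total)
}

#' Totals for a per-chromosome rearrangement count table
#'
#' Appends a totals row (column sums) to a per-chromosome count table whose
#' inversion columns come in `inv_total_*` / `inv_small_*` pairs, formats
#' inversion cells as `"total(small)"`, and computes the grand total of
#' large inversions, i.e. the sum over comparisons of (total - small).
#'
#' @param counts data frame with a `chrom` column and numeric count columns
#'   (`inv_total_*`, `inv_small_*`, and optionally `trans_*`).
#' @return list with `table` (formatted, totals row appended), `totals`
#'   (named numeric vector of column sums) and `large_inversion_total`.
#' @export
rearrangement_totals <- function(counts) {
  stopifnot("chrom" %in% names(counts))
  num <- setdiff(names(counts), "chrom")
  if (!length(num) || !nrow(counts))
    return(list(table = counts, totals = stats::setNames(numeric(), character()),
                large_inversion_total = 0))
  totals <- vapply(counts[num], sum, numeric(1))
  tot_cols <- grep("^inv_total_", num, value = TRUE)
  large <- sum(vapply(tot_cols, function(tc) {
    sc <- sub("^inv_total_", "inv_small_", tc)
    totals[[tc]] - if (sc %in% num) totals[[sc]] else 0
  }, numeric(1)))

  fmt <- data.frame(chrom = c(counts$chrom, "Total"))
  all_counts <- rbind(counts[num], as.list(totals))
  for (tc in tot_cols) {
    sc <- sub("^inv_total_", "inv_small_", tc)
    small <- if (sc %in% num) all_counts[[sc]] else rep(0, nrow(all_counts))
    fmt[[sub("^inv_total_", "inversion_", tc)]] <-
      sprintf("%d(%d)", as.integer(all_counts[[tc]]), as.integer(small))
  }
  for (cn in grep("^trans_", num, value = TRUE))
    fmt[[cn]] <- all_counts[[cn]]
  list(table = fmt, totals = totals, large_inversion_total = large)
}
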