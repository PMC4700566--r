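#' Intersect alignment hits with ancestral-block intervals
#'
#' Each hit contributes the block whose interval contains the hit midpoint on
#' the matching reference chromosome (blocks are megabase-scale while marker
#' hits are tens of bp, so the midpoint is unambiguous). Hits outside every
#' block interval contribute no candidate.
#'
#' @param hits alignment data frame with `subject_chrom` (or `sseqid`),
#'   `subject_start`, `subject_end`.
#' @param block_defs block definitions from [read_block_defs()].
#' @return `hits` with an added `block` column (`NA` when outside all blocks).
#' @export
hits_to_blocks <- function(hits, block_defs) {
  chrom <- if ("subject_chrom" %in% names(hits)) hits$subject_chrom
           else hits$sseqid
  mid <- (hits$subject_start + hits$subject_end) / 2
  hits$block <- NA_character_
  for (i in seq_len(nrow(block_defs))) {
    b <- block_defs[i, ]
    inside <- chrom == b$chrom & mid >= b$start & mid <= b$end
    hits$block[inside & is.na(hits$block)] <- b$block
  }
  hits
}

#' Assign mapped loci to ancestral karyotype blocks
#'
#' Each locus on the genetic map may carry several filtered alignment hits,
#' hence several candidate blocks. Candidates are scored by ordered criteria,
#' the first criterion that discriminates winning: (1) the block agreeing
#' with both flanking assigned loci; (2) the block supported by the most
#' distinct co-bin member markers of the locus; (3) longest match; (4)
#' smallest E-value; (5) highest percent identity. Assignment runs in two
#' passes: a provisional pass using criteria (2)-(5), then a second pass that
#' re-checks adjacency against the provisional assignments of the nearest
#' assigned neighbours on the same linkage group. Loci left tied on all
#' criteria stay unassigned and are flagged.
#'
#' @param loci genetic-map data frame (`locus_id`, `lg`, `position_cm`),
#'   ordered along each linkage group.
#' @param hits alignment data frame with columns `locus_id`, `marker_id`,
#'   `block` (from [hits_to_blocks()]; `NA` blocks are ignored), `length`,
#'   `evalue`, `pident`.
#' @return data frame, one row per locus: `locus_id`, `lg`, `position_cm`,
#'   `block` (`NA` if unassigned), `n_support` (hits supporting the assigned
#'   block), `support_identity` (minimum percent identity among those hits),
#'   `adjacency_consistent`, `tie_unresolved`.
#' @export
assign_blocks <- function(loci, hits) {
  stopifnot(all(c("locus_id", "lg", "position_cm") %in% names(loci)),
            all(c("locus_id", "block", "length", "evalue", "pident")
                %in% names(hits)))
  if (!"marker_id" %in% names(hits)) hits$marker_id <- hits$locus_id
  hits <- hits[!is.na(hits$block), , drop = FALSE]

  # per-locus candidate table: one row per candidate block
  cand_of <- lapply(loci$locus_id, function(lid) {
    h <- hits[hits$locus_id == lid, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    do.call(rbind, lapply(split(h, h$block), function(hb) {
      data.frame(block = hb$block[1L],
                 support = length(unique(hb$marker_id)),
                 best_len = max(hb$length),
                 best_e = min(hb$evalue),
                 best_ident = max(hb$pident),
                 n_hits = nrow(hb),
                 min_ident = min(hb$pident))
    }))
  })
  names(cand_of) <- loci$locus_id

  # criteria (2)-(5): bin support, match length, E-value, identity
  pick_by_scores <- function(cand) {
    for (cn in c("support", "best_len", "best_e", "best_ident")) {
      v <- cand[[cn]]
      best <- if (cn == "best_e") v == min(v) else v == max(v)
      if (sum(best) == 1L) return(cand$block[best])
      cand <- cand[best, , drop = FALSE]
    }
    NA_character_  # tied on every criterion
  }

  assigned <- vapply(cand_of, function(cand) {
    if (is.null(cand)) NA_character_
    else if (nrow(cand) == 1L) cand$block
    else pick_by_scores(cand)
  }, character(1))

  # second pass: adjacency among provisional assignments within each lg
  final <- assigned
  adj_ok <- rep(NA, nrow(loci))
  for (g in unique(loci$lg)) {
    ix <- which(loci$lg == g)
    ix <- ix[order(loci$position_cm[ix])]
    a <- assigned[ix]
    has_cand <- !vapply(cand_of[ix], is.null, logical(1))
    for (k in seq_along(ix)) {
      if (!has_cand[k]) next
      prev <- k - 1L; while (prev >= 1L && is.na(a[prev])) prev <- prev - 1L
      nxt <- k + 1L; while (nxt <= length(ix) && is.na(a[nxt])) nxt <- nxt + 1L
      lblk <- if (prev >= 1L) a[prev] else NA
      rblk <- if (nxt <= length(ix)) a[nxt] else NA
      cand <- cand_of[[ix[k]]]
      if (!is.na(lblk) && !is.na(rblk) && lblk == rblk &&
          lblk %in% cand$block) {
        final[ix[k]] <- lblk
      }
      adj_ok[ix[k]] <- !is.na(final[ix[k]]) &&
        ((!is.na(lblk) && lblk == final[ix[k]]) ||
         (!is.na(rblk) && rblk == final[ix[k]]))
    }
  }

  n_support <- integer(nrow(loci))
  sup_ident <- rep(NA_real_, nrow(loci))
  for (k in seq_len(nrow(loci))) {
    cand <- cand_of[[k]]
    if (is.null(cand) || is.na(final[k])) next
    row <- cand[cand$block == final[k], , drop = FALSE]
    n_support[k] <- row$n_hits
    sup_ident[k] <- row$min_ident
  }
  data.frame(locus_id = loci$locus_id, lg = loci$lg,
             position_cm = loci$position_cm, block = unname(final),
             n_support = n_support, support_identity = sup_ident,
             adjacency_consistent = unname(adj_ok),
             tie_unresolved = !vapply(cand_of, is.null, logical(1)) &
               is.na(unname(final)),
             row.names = NULL)
}

#' Call synteny blocks and small insertions along linkage groups
#'
#' At least three consecutive loci assigned to the same ancestral block form
#' a synteny block. A run of one or two loci is called a small insertion only
#' when all its supporting hits have nearly perfect identity (at least
#' `identity_floor` percent); other short runs yield no call. Unassigned loci
#' are transparent by default - they do not break runs, since typically only
#' a minority of mapped loci align to the reference - but `strict = TRUE`
#' makes them break runs.
#'
#' @param assignments output of [assign_blocks()] (ordered within each lg by
#'   `position_cm`).
#' @param identity_floor minimum percent identity for an insertion call.
#' @param strict when `TRUE`, unassigned loci terminate runs.
#' @return data frame of calls: `lg`, `block`, `first_locus`, `last_locus`,
#'   `first_cm`, `last_cm`, `span_cm`, `n_loci`, `kind`
#'   (`"synteny_block"` or `"insertion"`).
#' @export
#' @examples
#' a <- data.frame(locus_id = paste0("L", 1:7), lg = "A05",
#'                 position_cm = 1:7,
#'                 block = c("J", "J", "J", "C", "J", "J", "J"),
#'                 support_identity = c(95, 96, 97, 100, 95, 96, 97))
#' call_synteny_blocks(a)  # two J synteny blocks plus a C insertion
call_synteny_blocks <- function(assignments, identity_floor = 99,
                                strict = FALSE) {
  stopifnot(all(c("lg", "block", "position_cm") %in% names(assignments)))
  if (!"support_identity" %in% names(assignments))
    assignments$support_identity <- NA_real_
  out <- list()
  for (g in unique(assignments$lg)) {
    d <- assignments[assignments$lg == g, , drop = FALSE]
    d <- d[order(d$position_cm), , drop = FALSE]
    if (!strict) d <- d[!is.na(d$block), , drop = FALSE]
    if (nrow(d) == 0L) next
    r <- rle(ifelse(is.na(d$block), "<NA>", d$block))
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == "<NA>") next
      run <- d[starts[j]:stops[j], , drop = FALSE]
      n <- nrow(run)
      kind <- if (n >= 3L) "synteny_block"
        else if (all(!is.na(run$support_identity)) &&
                 all(run$support_identity >= identity_floor)) "insertion"
        else NA_character_
      if (is.na(kind)) next
      out[[length(out) + 1L]] <- data.frame(
        lg = g, block = r$values[j],
        first_locus = run$locus_id[1L], last_locus = run$locus_id[n],
        first_cm = run$position_cm[1L], last_cm = run$position_cm[n],
        span_cm = run$position_cm[n] - run$position_cm[1L],
        n_loci = n, kind = kind)
    }
  }
  if (!length(out))
    return(data.frame(lg = character(), block = character(),
                      first_locus = character(), last_locus = character(),
                      first_cm = numeric(), last_cm = numeric(),
                      span_cm = numeric(), n_loci = integer(),
                      kind = character()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify markers by genome specificity
#'
#' Given stringently filtered hits (the `"genome"` profile of
#' [alignment_filter_profile()]), a marker is `unique_A` / `unique_B` /
#' `unique_C` when all its hits fall on that one basic Brassica genome at
#' exactly one location, `multi` when it hits two or more genomes or two or
#' more locations, and `unaligned` when it has no retained hit.
#'
#' @param hits data frame with `marker_id` (or `qseqid`) and `genome`
#'   (labels `"A"`, `"B"`, `"C"`); one row per hit location.
#' @param marker_ids full marker universe (so unaligned markers are counted);
#'   defaults to the markers present in `hits`.
#' @return data frame `marker_id`, `class`.
#' @export
genome_specificity <- function(hits, marker_ids = NULL) {
  if (!"marker_id" %in% names(hits)) hits$marker_id <- hits$qseqid
  stopifnot("genome" %in% names(hits))
  if (is.null(marker_ids)) marker_ids <- unique(hits$marker_id)
  cls <- vapply(marker_ids, function(m) {
    h <- hits[hits$marker_id == m, , drop = FALSE]
    if (nrow(h) == 0L) return("unaligned")
    g <- unique(h$genome)
    if (length(g) > 1L || nrow(h) > 1L) return("multi")
    paste0("unique_", g)
  }, character(1))
  data.frame(marker_id = marker_ids, class = unname(cls))
}
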