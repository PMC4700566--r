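#' Quality-control profile for genotyping-by-sequencing markers
#'
#' Marker retention rules used throughout the pipeline. Two named presets
#' reproduce the study designs this package targets: `"mapping"` (an F2
#' mapping population; missing-data rate at most 10%, with bin-representative
#' markers held to at most 5%) and `"diversity"` (a diversity panel;
#' missing-data rate at most 5%). In both presets markers must have a call
#' rate strictly above 0.90, and SNP markers a quality score (Q, the log of
#' the minimum FDR at which the call is significant) strictly above 2.0.
#'
#' @param preset `"mapping"` or `"diversity"`.
#' @param min_call_rate minimum call rate, exclusive bound (marker kept when
#'   `call_rate > min_call_rate`).
#' @param min_q minimum Q score for SNP markers, exclusive bound.
#' @param max_missing maximum missing-data fraction, inclusive bound.
#'   Defaults to 0.10 for `"mapping"`, 0.05 for `"diversity"`.
#' @param bin_rep_max_missing maximum missing fraction for a bin
#'   representative marker (mapping preset only; inclusive).
#' @return an object of class `qc_profile`.
#' @export
#' @examples
#' qc_profile("diversity")
qc_profile <- function(preset = c("mapping", "diversity"),
                       min_call_rate = 0.90, min_q = 2.0,
                       max_missing = NULL,
                       bin_rep_max_missing = 0.05) {
  preset <- match.arg(preset)
  if (is.null(max_missing))
    max_missing <- switch(preset, mapping = 0.10, diversity = 0.05)
  structure(
    list(preset = preset, min_call_rate = min_call_rate, min_q = min_q,
         max_missing = max_missing, bin_rep_max_missing = bin_rep_max_missing),
    class = "qc_profile")
}

#' @export
print.qc_profile <- function(x, ...) {
  cat(sprintf(
    "QC profile '%s': call rate > %g, Q > %g (SNP), missing <= %g\n",
    x$preset, x$min_call_rate, x$min_q, x$max_missing))
  invisible(x)
}

#' Filter markers by quality-control rules
#'
#' Applies a [qc_profile()] to a marker table: retains markers whose call rate
#' exceeds the profile threshold (strict), whose missing-data fraction does
#' not exceed the profile bound (inclusive), and - for codominant SNP markers -
#' whose Q score exceeds the profile threshold (strict). A SNP marker with no
#' Q score cannot be evaluated and is rejected with a message rather than
#' aborting the run. Row order is preserved and the input is not modified;
#' filtering is idempotent.
#'
#' @param markers data frame with columns `id`, `marker_type` (one of
#'   `"dominant_presence_absence"`, `"codominant_snp"`), `call_rate`, and
#'   optionally `q_score` and `missing_rate`. When `missing_rate` is absent it
#'   is taken as `1 - call_rate`.
#' @param profile a [qc_profile()].
#' @return the retained subset of `markers`, in input order.
#' @export
#' @examples
#' m <- data.frame(id = c("m1", "m2"),
#'                 marker_type = "codominant_snp",
#'                 call_rate = c(0.95, 0.90), q_score = c(2.5, 3))
#' filter_markers(m, qc_profile("diversity"))  # m2 fails the strict 0.90 bound
filter_markers <- function(markers, profile = qc_profile("mapping")) {
  stopifnot(is.data.frame(markers), inherits(profile, "qc_profile"))
  need <- c("id", "marker_type", "call_rate")
  miss <- setdiff(need, names(markers))
  if (length(miss))
    stop("markers is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(markers) == 0L) return(markers)

  missing_rate <- if ("missing_rate" %in% names(markers))
    markers$missing_rate else 1 - markers$call_rate
  keep <- markers$call_rate > profile$min_call_rate &
    missing_rate <= profile$max_missing
  is_snp <- markers$marker_type == "codominant_snp"
  if (any(is_snp)) {
    q <- if ("q_score" %in% names(markers)) markers$q_score
         else rep(NA_real_, nrow(markers))
    no_q <- is_snp & is.na(q)
    if (any(no_q))
      message(sum(no_q), " SNP marker(s) without a Q score rejected")
    keep[is_snp] <- keep[is_snp] & !is.na(q[is_snp]) & q[is_snp] > profile$min_q
  }
  keep[is.na(keep)] <- FALSE
  markers[keep, , drop = FALSE]
}

#' Marker bookkeeping for a mapping experiment
#'
#' Arithmetic accounting of where the selected markers ended up: how many
#' could not be linked to any linkage group, and what share of mapped loci
#' are single-marker loci.
#'
#' @param n_selected markers selected for map construction.
#' @param n_mapped markers placed on the map.
#' @param n_single_loci single-marker loci on the map.
#' @param n_total_loci total loci on the map.
#' @return list with `unlinked` (count) and `single_locus_share_pct`
#'   (percentage, rounded to the nearest integer as conventionally reported).
#' @export
marker_accounting <- function(n_selected, n_mapped, n_single_loci, n_total_loci) {
  stopifnot(n_selected >= n_mapped, n_total_loci >= n_single_loci,
            n_total_loci > 0)
  list(unlinked = n_selected - n_mapped,
       single_locus_share_pct = round(100 * n_single_loci / n_total_loci))
}
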