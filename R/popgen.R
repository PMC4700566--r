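#' Per-group allele (or band-state) frequencies
#'
#' For codominant markers scored as alt-allele dosage (0/1/2), the
#' alt-allele frequency in a group is the dosage sum divided by twice the
#' number of non-missing calls. Dominant presence/absence markers (0/1) are
#' scored on band-state frequencies: the presence frequency among non-missing
#' calls (no Hardy-Weinberg correction is attempted; see the package
#' vignette for why). Markers with no data in a group get `NA` and are
#' excluded pairwise by [nei_distance()].
#'
#' @param calls numeric matrix, markers x accessions; dosage 0/1/2
#'   (codominant) or 0/1 (dominant); `NA` missing.
#' @param groups factor or character vector of group labels, one per
#'   accession (matrix column).
#' @param marker_type `"codominant_snp"` or `"dominant_presence_absence"`,
#'   recycled over markers.
#' @return list with `freq` (markers x groups matrix of alt/presence
#'   frequencies) and `n` (matrix of non-missing sample sizes).
#' @export
allele_freqs <- function(calls, groups,
                         marker_type = "codominant_snp") {
  if (length(groups) == 0L) stop("empty group")
  stopifnot(is.matrix(calls), length(groups) == ncol(calls))
  groups <- as.character(groups)
  marker_type <- rep_len(marker_type, nrow(calls))
  ploidy <- ifelse(marker_type == "codominant_snp", 2, 1)
  gl <- sort(unique(groups))
  freq <- n <- matrix(NA_real_, nrow(calls), length(gl),
                      dimnames = list(rownames(calls), gl))
  for (g in gl) {
    sub <- calls[, groups == g, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    freq[, g] <- ifelse(nn > 0, s / (ploidy * nn), NA_real_)
    n[, g] <- nn
  }
  list(freq = freq, n = n)
}

#' Nei (1972) standard genetic distance between two groups
#'
#' For biallelic loci with allele frequencies `px`, `py` (frequency of the
#' same reference allele in each group), the identity sums are
#' `Jxy = mean(px*py + (1-px)*(1-py))`, `Jx = mean(px^2 + (1-px)^2)` and
#' `Jy` likewise, averaged over loci with data in both groups, and
#' `D = -ln(Jxy / sqrt(Jx * Jy))`. Groups fixed for opposite alleles at
#' every shared locus give `Jxy = 0` and the `+Inf` sentinel.
#'
#' @param px,py numeric vectors of reference-allele frequencies over the
#'   same markers; `NA` entries are excluded pairwise.
#' @return nonnegative number (possibly `Inf`).
#' @export
#' @examples
#' nei_distance(c(0.5, 1), c(0.5, 0.5))  # ~0.2027
nei_distance <- function(px, py) {
  stopifnot(length(px) == length(py))
  ok <- !is.na(px) & !is.na(py)
  if (!any(ok)) stop("no shared markers with data in both groups")
  px <- px[ok]; py <- py[ok]
  jxy <- mean(px * py + (1 - px) * (1 - py))
  jx <- mean(px^2 + (1 - px)^2)
  jy <- mean(py^2 + (1 - py)^2)
  if (jxy == 0) return(Inf)
  max(0, -log(jxy / sqrt(jx * jy)))
}

#' Pairwise Nei distance matrix over groups
#'
#' @param freq markers x groups frequency matrix (from [allele_freqs()]).
#' @return symmetric matrix with zero diagonal, labelled by group.
#' @export
nei_dist_matrix <- function(freq) {
  g <- colnames(freq)
  n <- ncol(freq)
  d <- matrix(0, n, n, dimnames = list(g, g))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- nei_distance(freq[, i], freq[, j])
  }
  d
}

#' Polymorphism rate within a group of accessions
#'
#' Fraction of markers showing two or more distinct non-missing states
#' within the group, among markers with at least one non-missing call.
#'
#' @param calls numeric matrix, markers x accessions.
#' @param group optional logical/integer/character index of columns to use;
#'   defaults to all.
#' @return fraction in `[0, 1]`.
#' @export
polymorphism_rate <- function(calls, group = NULL) {
  if (!is.null(group)) {
    calls <- if (is.character(group))
      calls[, colnames(calls) %in% group, drop = FALSE]
    else calls[, group, drop = FALSE]
  }
  if (ncol(calls) == 0L) stop("empty group")
  states <- apply(calls, 1L, function(x) length(unique(x[!is.na(x)])))
  informative <- states >= 1L
  if (!any(informative)) return(0)
  mean(states[informative] >= 2L)
}

#' Evanno delta-K from admixture-run log-likelihoods
#'
#' Consumes replicate log-probabilities L(K) exported from an external
#' admixture/STRUCTURE-style program and computes the Evanno et al. (2005)
#' statistic for each interior K of a contiguous range:
#' `deltaK(K) = mean over replicates of |L(K+1) - 2 L(K) + L(K-1)|` divided
#' by the standard deviation of the L(K) replicates. K values whose
#' neighbours are absent are omitted; a zero replicate standard deviation at
#' an interior K is an error.
#'
#' @param runs data frame with columns `K`, `replicate`, `ln_prob`;
#'   replicates are paired across K by their `replicate` id.
#' @return data frame `K`, `mean_ln_prob`, `sd_ln_prob`, `delta_k`, for
#'   interior K only (may have zero rows).
#' @export
#' @examples
#' runs <- expand.grid(K = 1:4, replicate = 1:3)
#' runs$ln_prob <- -100 * runs$K          # exactly linear: delta K all 0
#' evanno_delta_k(runs)
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "replicate", "ln_prob") %in% names(runs)))
  ks <- sort(unique(runs$K))
  interior <- ks[(ks - 1) %in% ks & (ks + 1) %in% ks]
  out <- lapply(interior, function(k) {
    lk <- runs[runs$K == k, ]
    s <- stats::sd(lk$ln_prob)
    if (length(lk$ln_prob) < 2L || is.na(s))
      stop("need >= 2 replicates at K = ", k)
    if (s == 0) stop("zero replicate standard deviation at K = ", k)
    reps <- Reduce(intersect, list(runs$replicate[runs$K == k - 1],
                                   lk$replicate,
                                   runs$replicate[runs$K == k + 1]))
    l_at <- function(kk, r) runs$ln_prob[runs$K == kk & runs$replicate == r][1L]
    d2 <- vapply(reps, function(r)
      abs(l_at(k + 1, r) - 2 * l_at(k, r) + l_at(k - 1, r)), numeric(1))
    data.frame(K = k, mean_ln_prob = mean(lk$ln_prob), sd_ln_prob = s,
               delta_k = mean(d2) / s)
  })
  if (!length(out))
    return(data.frame(K = integer(), mean_ln_prob = numeric(),
                      sd_ln_prob = numeric(), delta_k = numeric()))
  do.call(rbind, out)
}

#' Read admixture-run summaries
#'
#' TSV with columns `K`, `replicate`, `ln_prob`.
#'
#' @param path file path.
#' @return data frame suitable for [evanno_delta_k()].
#' @export
read_structure_runs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("K", "replicate", "ln_prob") %in% names(d)))
  d
}
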