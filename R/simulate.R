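#' Map functions: cM to recombination fraction
#'
#' Haldane (no interference): `r = (1 - exp(-2 d / 100)) / 2`. Kosambi:
#' `r = tanh(2 d / 100) / 2`.
#'
#' @param d_cm distance in cM.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

#' @rdname haldane_r
#' @export
kosambi_r <- function(d_cm) tanh(2 * d_cm / 100) / 2

#' Simulate an F2 genotype matrix from a map specification
#'
#' Generates an F2 population by simulating two gametes per individual and
#' linkage group. The first marker allele of a gamete is drawn at random and
#' recombination between adjacent markers occurs with the Haldane (default)
#' or Kosambi probability for the inter-marker distance - no crossover
#' interference. Codominant markers report genotype codes `A`/`H`/`B`;
#' dominant presence/absence markers collapse the heterozygote with the
#' presence class (codes `1`/`0`), giving the Mendelian 3:1 expectation.
#' Missingness is applied completely at random at `missing_rate`.
#' Segregation distortion is modelled as gametic selection: at a distorted
#' locus a gamete carrying the disfavoured (second-parent) allele survives
#' with probability `1 - s` and is redrawn otherwise.
#'
#' Markers at identical positions co-segregate exactly (before missingness),
#' so they fall into one bin under [classify_bins()]; the planted bin
#' partition is returned as truth.
#'
#' @param map_spec data frame with columns `marker_id`, `lg`, `pos_cm`, and
#'   optionally `type` (`"codominant_snp"` default, or
#'   `"dominant_presence_absence"`).
#' @param n number of F2 individuals.
#' @param seed RNG seed (mandatory; generation is seed-deterministic).
#' @param missing_rate missing-call probability, in `[0, 1]`.
#' @param distortion optional data frame `lg`, `pos_cm`, `s` of distorted
#'   loci and their gametic selection coefficients.
#' @param map_fun `"haldane"` or `"kosambi"`.
#' @return list with `calls` (character matrix markers x individuals, codes
#'   as above with `NA` missing), `dosage` (numeric matrix, second-parent
#'   allele count 0/1/2 before collapsing/missingness), `info` (marker data
#'   frame) and `truth` (list: `bins` = planted bin partition by identical
#'   position, `gametes` = the simulated gamete haplotypes (markers x 2n),
#'   `spec`, `seed`).
#' @export
simulate_f2 <- function(map_spec, n, seed, missing_rate = 0,
                        distortion = NULL,
                        map_fun = c("haldane", "kosambi")) {
  map_fun <- match.arg(map_fun)
  if (n < 1) stop("n must be >= 1")
  stopifnot(all(c("marker_id", "lg", "pos_cm") %in% names(map_spec)),
            missing_rate >= 0, missing_rate <= 1)
  if (!"type" %in% names(map_spec)) map_spec$type <- "codominant_snp"
  rfun <- switch(map_fun, haldane = haldane_r, kosambi = kosambi_r)

  with_seed(seed, {
    dosage <- matrix(NA_real_, nrow(map_spec), n,
                     dimnames = list(map_spec$marker_id, NULL))
    gametes <- matrix(NA_integer_, nrow(map_spec), 2L * n,
                      dimnames = list(map_spec$marker_id, NULL))
    for (g in unique(map_spec$lg)) {
      ix <- which(map_spec$lg == g)
      ix <- ix[order(map_spec$pos_cm[ix])]
      pos <- map_spec$pos_cm[ix]
      m <- length(ix)
      r <- if (m > 1) rfun(diff(pos)) else numeric()
      dist_s <- rep(0, m)
      if (!is.null(distortion)) {
        dl <- distortion[distortion$lg == g, , drop = FALSE]
        for (q in seq_len(nrow(dl))) {
          at <- which(abs(pos - dl$pos_cm[q]) < 1e-9)
          dist_s[at] <- dl$s[q]
        }
      }
      gamete <- function() {
        repeat {
          al <- integer(m)
          al[1L] <- stats::rbinom(1L, 1L, 0.5)
          if (m > 1) {
            sw <- stats::rbinom(m - 1L, 1L, r)
            al <- cumsum(c(al[1L], sw)) %% 2L
          }
          # gametic selection: disfavoured allele (1) survives w.p. 1 - s
          sel <- which(dist_s > 0 & al == 1L)
          if (!length(sel) ||
              all(stats::runif(length(sel)) < 1 - dist_s[sel]))
            return(al)
        }
      }
      for (ind in seq_len(n)) {
        g1 <- gamete(); g2 <- gamete()
        dosage[ix, ind] <- g1 + g2
        gametes[ix, 2L * ind - 1L] <- g1
        gametes[ix, 2L * ind] <- g2
      }
    }
    calls <- matrix(NA_character_, nrow(map_spec), n,
                    dimnames = list(map_spec$marker_id, NULL))
    codom <- map_spec$type == "codominant_snp"
    calls[codom, ] <- c("A", "H", "B")[dosage[codom, , drop = FALSE] + 1]
    calls[!codom, ] <-
      ifelse(dosage[!codom, , drop = FALSE] >= 1, "1", "0")
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(length(calls)) < missing_rate,
                     nrow(calls))
      calls[drop] <- NA_character_
    }
    key <- paste(map_spec$lg, format(map_spec$pos_cm, digits = 12))
    truth_bins <- split(map_spec$marker_id, key)
    list(calls = calls, dosage = dosage, info = map_spec,
         truth = list(bins = unname(truth_bins), gametes = gametes,
                      seed = seed, spec = map_spec))
  })
}

#' Simulate anchor sets between two genomes with planted rearrangements
#'
#' Generates, per chromosome, evenly spaced anchors with uniform positional
#' jitter (collinear between the two genomes), then plants inversions by
#' reversing the partner-genome order of the anchors inside each specified
#' interval, and translocations by reassigning a run of anchors to a
#' different partner chromosome. Planted events must not overlap.
#'
#' @param chromosomes data frame `chrom`, `length_bp`, `n_anchors`.
#' @param inversions optional data frame `chrom`, `start_bp`, `end_bp`.
#' @param translocations optional data frame `chrom`, `target_chrom`,
#'   `start_index`, `run_length`.
#' @param seed RNG seed.
#' @param jitter_frac jitter amplitude as a fraction of anchor spacing
#'   (must stay below 0.5 to preserve collinear order).
#' @return list with `anchors` (data frame `id`, `chrom_a`, `coord_a`,
#'   `chrom_b`, `coord_b`, `identity`, `unique_b`) and `truth` (the planted
#'   event tables).
#' @export
simulate_rearranged_genomes <- function(chromosomes, inversions = NULL,
                                        translocations = NULL, seed = 1,
                                        jitter_frac = 0.25) {
  stopifnot(all(c("chrom", "length_bp", "n_anchors") %in% names(chromosomes)),
            jitter_frac >= 0, jitter_frac < 0.5)
  # planted events on one chromosome must not overlap
  if (!is.null(inversions) && !is.null(translocations)) {
    for (ch in unique(inversions$chrom)) {
      inv <- inversions[inversions$chrom == ch, , drop = FALSE]
      tr <- translocations[translocations$chrom == ch, , drop = FALSE]
      if (nrow(inv) && nrow(tr)) {
        n_anch <- chromosomes$n_anchors[chromosomes$chrom == ch]
        spacing <- chromosomes$length_bp[chromosomes$chrom == ch] / (n_anch + 1)
        for (q in seq_len(nrow(tr))) {
          t_start <- tr$start_index[q] * spacing
          t_end <- (tr$start_index[q] + tr$run_length[q] - 1) * spacing
          if (any(inv$start_bp <= t_end & inv$end_bp >= t_start))
            stop("planted events overlap on ", ch)
        }
      }
    }
  }
  with_seed(seed, {
    anchors <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
      ch <- chromosomes[i, ]
      spacing <- ch$length_bp / (ch$n_anchors + 1)
      coord_a <- spacing * seq_len(ch$n_anchors)
      coord_b <- coord_a + stats::runif(ch$n_anchors, -jitter_frac, jitter_frac) * spacing
      data.frame(id = sprintf("%s_g%03d", ch$chrom, seq_len(ch$n_anchors)),
                 chrom_a = ch$chrom, coord_a = coord_a,
                 chrom_b = ch$chrom, coord_b = coord_b,
                 identity = 100, unique_b = TRUE)
    }))
    if (!is.null(inversions)) for (q in seq_len(nrow(inversions))) {
      ev <- inversions[q, ]
      sel <- which(anchors$chrom_a == ev$chrom &
                   anchors$coord_a >= ev$start_bp &
                   anchors$coord_a <= ev$end_bp)
      if (length(sel) >= 2L)
        anchors$coord_b[sel] <- rev(anchors$coord_b[sel])
    }
    if (!is.null(translocations)) for (q in seq_len(nrow(translocations))) {
      ev <- translocations[q, ]
      d <- which(anchors$chrom_a == ev$chrom)
      sel <- d[seq(ev$start_index, length.out = ev$run_length)]
      anchors$chrom_b[sel] <- ev$target_chrom
    }
    list(anchors = anchors,
         truth = list(inversions = inversions,
                      translocations = translocations, seed = seed))
  })
}

#' Simulate a structured diversity panel (Balding-Nichols model)
#'
#' Ancestral allele frequencies are drawn per locus from Uniform(0.05,
#' 0.95); each of K populations draws its frequency from the Balding-Nichols
#' Beta distribution `Beta(p (1-F)/F, (1-p)(1-F)/F)` with divergence
#' parameter F; an accession's expected frequency is its membership-weighted
#' mix of population frequencies; genotypes are Binomial(2, freq) dosages.
#'
#' @param K number of populations.
#' @param F_div divergence parameter per population, in (0, 1); recycled.
#' @param L number of loci.
#' @param n_per_pop accessions per population; recycled over populations.
#' @param admixture optional matrix of extra accessions x K membership rows
#'   (each summing to 1) appended after the pure-population accessions.
#' @param seed RNG seed.
#' @return list with `calls` (dosage matrix, loci x accessions),
#'   `accessions` (data frame `code`, `population`; admixed accessions are
#'   labelled `"admixed"`), and `truth` (ancestral and population
#'   frequencies, memberships, seed).
#' @export
simulate_panel <- function(K, F_div, L, n_per_pop, admixture = NULL,
                           seed = 1) {
  F_div <- rep_len(F_div, K)
  if (any(F_div <= 0 | F_div >= 1)) stop("F must be in (0, 1)")
  n_per_pop <- rep_len(n_per_pop, K)
  with_seed(seed, {
    p_anc <- stats::runif(L, 0.05, 0.95)
    pop_freq <- sapply(seq_len(K), function(k) {
      a <- p_anc * (1 - F_div[k]) / F_div[k]
      b <- (1 - p_anc) * (1 - F_div[k]) / F_div[k]
      stats::rbeta(L, a, b)
    })
    Q <- do.call(rbind, lapply(seq_len(K), function(k) {
      m <- matrix(0, n_per_pop[k], K); m[, k] <- 1; m
    }))
    pop_label <- rep(paste0("pop", seq_len(K)), n_per_pop)
    if (!is.null(admixture)) {
      admixture <- as.matrix(admixture)
      if (ncol(admixture) != K || any(abs(rowSums(admixture) - 1) > 1e-9))
        stop("admixture rows must have K entries summing to 1")
      Q <- rbind(Q, admixture)
      pop_label <- c(pop_label, rep("admixed", nrow(admixture)))
    }
    n_acc <- nrow(Q)
    freq <- pop_freq %*% t(Q)              # L x n_acc expected frequencies
    calls <- matrix(stats::rbinom(L * n_acc, 2L, as.vector(freq)), L, n_acc)
    codes <- sprintf("acc%02d", seq_len(n_acc))
    dimnames(calls) <- list(sprintf("L%04d", seq_len(L)), codes)
    list(calls = calls,
         accessions = data.frame(code = codes, population = pop_label),
         truth = list(p_anc = p_anc, pop_freq = pop_freq, Q = Q,
                      seed = seed))
  })
}
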