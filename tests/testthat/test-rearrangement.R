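res168 <- resolution_model(168)

test_that("collinear anchors yield no inversion events", {
  anch <- data.frame(id = paste0("a", 1:6), chrom_a = "A01", coord_a = 0:5,
                     chrom_b = "A01", coord_b = (0:5) * 1e6)
  ev <- detect_inversions(anch, res168, "genetic")
  expect_equal(nrow(ev), 0)
  expect_false(attr(ev, "orientation_flip"))
})

test_that("a reversed interior cluster is called with the right span class", {
  # middle three of five anchors reversed in physical order, span 2.0 cM
  anch <- data.frame(id = paste0("a", 1:5), chrom_a = "A10",
                     coord_a = c(0, 1, 2, 3, 4), chrom_b = "A10",
                     coord_b = c(0, 3, 2, 1, 4) * 1e6)
  ev <- detect_inversions(anch, res168, "genetic")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_anchors, 3)
  expect_equal(ev$span_a, 2)
  expect_equal(ev$size_class, "large")  # 2.0 cM > 1.2 cM
  # brute force: the called anchors are exactly the order-reversed ones
  expect_equal(ev$anchor_ids, "a2,a3,a4")
})

test_that("inversion span thresholds follow the resolution model", {
  pair <- function(span) data.frame(
    id = c("l", "x", "y", "r"), chrom_a = "A02",
    coord_a = c(0, 1, 1 + span, 10), chrom_b = "A02",
    coord_b = c(0, 3e6, 2e6, 10e6))
  # reversed pair spanning 0.8 cM: small inversion (between 0.6 and 1.2 cM)
  ev <- detect_inversions(pair(0.8), res168, "genetic")
  expect_equal(ev$size_class, "small")
  # spanning 0.5 cM: below the permitted-error distance, no event
  expect_equal(nrow(detect_inversions(pair(0.5), res168, "genetic")), 0)
  # spanning 1.3 cM: large
  expect_equal(detect_inversions(pair(1.3), res168, "genetic")$size_class,
               "large")
})

test_that("physical-unit calls use the 1 Mb small/large boundary", {
  anch <- data.frame(id = paste0("g", 1:6), chrom_a = "A07",
                     coord_a = c(0, 1, 1.4, 2, 6, 11) * 1e6, chrom_b = "A07",
                     coord_b = c(0, 1.4, 1, 2, 11, 6) * 1e6)
  ev <- detect_inversions(anch, unit = "physical")
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$size_class), c("large", "small"))
  expect_equal(ev$span_a[ev$size_class == "small"], 0.4e6)
})

test_that("whole-chromosome reversal is an orientation flip, not an inversion", {
  anch <- data.frame(id = paste0("a", 1:5), chrom_a = "A01", coord_a = 0:4,
                     chrom_b = "A01", coord_b = (4:0) * 1e6)
  ev <- detect_inversions(anch, res168, "genetic")
  expect_equal(nrow(ev), 0)
  expect_true(attr(ev, "orientation_flip"))
})

test_that("inversion detection is strand-symmetric and events never share anchors", {
  set.seed(13)
  for (seed in 1:4) {
    set.seed(seed)
    n <- 20
    coord_b <- sample(n) * 1e6
    anch <- data.frame(id = paste0("a", 1:n), chrom_a = "A01",
                       coord_a = seq(0, by = 1.5, length.out = n),
                       chrom_b = "A01", coord_b = coord_b)
    fwd <- detect_inversions(anch, res168, "genetic")
    anch_rev <- anch
    anch_rev$coord_b <- max(coord_b) + 1e6 - coord_b
    rev_ev <- detect_inversions(anch_rev, res168, "genetic")
    # anchor membership within each orientation is disjoint
    for (ev in list(fwd, rev_ev)) {
      if (nrow(ev) < 2) next
      ids <- strsplit(ev$anchor_ids, ",")
      expect_equal(anyDuplicated(unlist(ids)), 0)
    }
    # reversing orientation converts decreasing runs into increasing ones:
    # no anchor pair can be jointly inverted in both orientations unless tied
    if (nrow(fwd) && nrow(rev_ev)) {
      pairs_of <- function(ev) unlist(lapply(strsplit(ev$anchor_ids, ","),
        function(v) apply(utils::combn(v, 2), 2, paste, collapse = "-")))
      expect_length(intersect(pairs_of(fwd), pairs_of(rev_ev)), 0)
    }
  }
})

test_that("co-located anchors share a rank and cannot form an inversion alone", {
  # two anchors in one bin (same cM): no rank change, no event
  anch <- data.frame(id = c("a", "b", "c"), chrom_a = "A01",
                     coord_a = c(0, 2, 2), chrom_b = "A01",
                     coord_b = c(1e6, 3e6, 2.5e6))
  expect_equal(nrow(detect_inversions(anch, res168, "genetic")), 0)
})

test_that("genome-pair translocations need more than four successive genes", {
  mk <- function(run_len) {
    n <- 20
    chrom_b <- rep("A01", n)
    chrom_b[8:(7 + run_len)] <- "A03"
    data.frame(id = paste0("g", 1:n), chrom_a = "A01",
               coord_a = (1:n) * 1e5, chrom_b = chrom_b)
  }
  # all concordant: nothing
  all_same <- data.frame(id = paste0("g", 1:10), chrom_a = "A01",
                         coord_a = (1:10) * 1e5, chrom_b = "A01")
  expect_equal(nrow(detect_translocations_genome_pair(all_same)), 0)
  # run of 5 -> one event A01 -> A03
  ev <- detect_translocations_genome_pair(mk(5))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$source_chrom, "A01")
  expect_equal(ev$target_chrom, "A03")
  # run of 4 -> no event under the default (strict "more than four")
  expect_equal(nrow(detect_translocations_genome_pair(mk(4))), 0)
  # min_run = 4 reinstates it
  expect_equal(nrow(detect_translocations_genome_pair(mk(4), min_run = 4)), 1)
})

test_that("planted genome-pair events are recovered with precision and recall 1", {
  chroms <- data.frame(chrom = c("A01", "A02", "A03"), length_bp = 30e6,
                       n_anchors = 40)
  inv <- data.frame(chrom = c("A01", "A02"), start_bp = c(5e6, 12e6),
                    end_bp = c(9e6, 16e6))
  tr <- data.frame(chrom = c("A02", "A03"), target_chrom = c("A05", "A06"),
                   start_index = c(30, 10), run_length = c(6, 7))
  sim <- simulate_rearranged_genomes(chroms, inv, tr, seed = 101)
  found_inv <- do.call(rbind, lapply(split(sim$anchors,
                                           sim$anchors$chrom_a), function(a) {
    a <- a[a$chrom_b == a$chrom_a[1], ]  # translocated anchors aside
    detect_inversions(a, unit = "physical")
  }))
  expect_equal(nrow(found_inv), nrow(inv))          # recall and precision 1
  expect_true(all(found_inv$size_class == "large")) # 4 Mb spans
  found_tr <- detect_translocations_genome_pair(sim$anchors, min_run = 5)
  expect_equal(nrow(found_tr), nrow(tr))
  expect_setequal(found_tr$target_chrom, tr$target_chrom)
  # below-threshold planted run is not recovered at the default
  tr4 <- data.frame(chrom = "A01", target_chrom = "A09",
                    start_index = 20, run_length = 4)
  sim4 <- simulate_rearranged_genomes(chroms, translocations = tr4, seed = 5)
  expect_equal(nrow(detect_translocations_genome_pair(sim4$anchors)), 0)
  expect_equal(nrow(detect_translocations_genome_pair(sim4$anchors,
                                                      min_run = 4)), 1)
})

test_that("map-based translocation candidates follow the 100%-unique rule", {
  map <- data.frame(locus_id = c("L1", "L2", "L3"), lg = "A04",
                    position_cm = c(0, 1, 2))
  hits <- data.frame(
    marker_id = c("m1", "m2", "m3", "m4"),
    locus_id = c("L1", "L1", "L2", "L3"),
    target_chrom = c("Ar03", "Ar07", "Ar03", "Ar03"),
    pident = 100, unique_b = TRUE)
  cand <- detect_translocations_map(map, hits)
  # bin locus L1 hits two chromosomes with unique 100% identity
  expect_equal(nrow(cand), 1)
  expect_equal(cand$locus_ids, "L1")
  expect_equal(cand$target_chroms, "Ar03,Ar07")
  expect_false(cand$confirmed)
  # identity below 100 or non-unique hits disqualify
  hits2 <- hits; hits2$pident[2] <- 99.9
  expect_equal(nrow(detect_translocations_map(map, hits2)), 0)
  hits3 <- hits; hits3$unique_b[2] <- FALSE
  expect_equal(nrow(detect_translocations_map(map, hits3)), 0)
  # adjacent-pair rule: two neighbouring single-chromosome loci that disagree
  hits4 <- data.frame(marker_id = c("m1", "m2"),
                      locus_id = c("L1", "L2"),
                      target_chrom = c("Ar03", "Ar07"),
                      pident = 100, unique_b = TRUE)
  cand4 <- detect_translocations_map(map, hits4)
  expect_equal(cand4$locus_ids, "L1,L2")
})

test_that("map-based candidates equal an exhaustive locus scan on a random fixture", {
  set.seed(17)
  map <- data.frame(locus_id = sprintf("L%02d", 1:30), lg = "A06",
                    position_cm = 1:30)
  hits <- do.call(rbind, lapply(1:30, function(i) {
    k <- sample(1:2, 1)
    data.frame(marker_id = paste0("m", i, "_", seq_len(k)),
               locus_id = map$locus_id[i],
               target_chrom = sample(c("Ar01", "Ar02"), k, replace = TRUE),
               pident = 100, unique_b = TRUE)
  }))
  cand <- detect_translocations_map(map, hits)
  # oracle: single-locus candidates
  single <- vapply(map$locus_id, function(l)
    length(unique(hits$target_chrom[hits$locus_id == l])) >= 2, logical(1))
  expect_equal(sum(cand$locus_ids %in% map$locus_id), sum(single))
})

test_that("perturbation confirms robust candidates and rejects fragile ones", {
  map <- data.frame(locus_id = paste0("L", 1:7), lg = "A04",
                    position_cm = 0:6)
  # robust: the bin locus itself carries hits to two chromosomes, so any
  # reordering of neighbours keeps the candidate
  hits_robust <- data.frame(marker_id = c("m1", "m2"),
                            locus_id = c("L4", "L4"),
                            target_chrom = c("Ar03", "Ar07"),
                            pident = 100, unique_b = TRUE)
  cand <- detect_translocations_map(map, hits_robust)
  expect_true(confirm_by_perturbation(map, hits_robust, cand[1, ],
                                      window = 2, n_reps = 20, seed = 42))
  # fragile: an adjacent-pair candidate whose loci can be separated
  hits_frag <- data.frame(marker_id = c("m1", "m2", "m3"),
                          locus_id = c("L3", "L4", "L5"),
                          target_chrom = c("Ar03", "Ar07", "Ar03"),
                          pident = 100, unique_b = TRUE)
  cand_f <- detect_translocations_map(map, hits_frag)
  pair <- cand_f[cand_f$locus_ids == "L3,L4", ]
  expect_false(confirm_by_perturbation(map, hits_frag, pair,
                                       window = 2, n_reps = 20, seed = 42))
  # zero replicates: vacuous confirmation with a flag
  v <- confirm_by_perturbation(map, hits_robust, cand[1, ], n_reps = 0)
  expect_true(v)
  expect_equal(attr(v, "flag"), "unperturbed")
})

test_that("event summaries reproduce published totals and independent tallies", {
  counts <- sypm_event_table()
  rt <- rearrangement_totals(counts)
  expect_equal(unname(rt$totals["inv_total_An-Ar"]), 62)
  expect_equal(unname(rt$totals["inv_total_Aj-Ar"]), 13)
  expect_equal(unname(rt$totals["inv_total_Aj-An"]), 15)
  expect_equal(unname(rt$totals[c("trans_Aj-Ar", "trans_Aj-An",
                                  "trans_Ar>An", "trans_An>Ar")]),
               c(2, 3, 15, 15))
  expect_equal(rt$large_inversion_total, 30)
  # formatted table carries "total(small)" cells and a totals row
  tot_row <- rt$table[rt$table$chrom == "Total", ]
  expect_equal(tot_row$`inversion_An-Ar`, "62(47)")

  # random event list: summary equals an independent tally
  set.seed(9)
  inv <- data.frame(comparison = sample(c("X-Y", "X-Z"), 50, replace = TRUE),
                    chrom = sample(paste0("A0", 1:3), 50, replace = TRUE),
                    size_class = sample(c("small", "large"), 50,
                                        replace = TRUE))
  tr <- data.frame(comparison = sample(c("X>Y", "Y>X"), 20, replace = TRUE),
                   source_chrom = sample(paste0("A0", 1:3), 20,
                                         replace = TRUE))
  s <- summarize_rearrangements(inv, tr)
  expect_equal(sum(s$counts$`inv_total_X-Y`),
               sum(inv$comparison == "X-Y"))
  expect_equal(sum(s$counts$`trans_X>Y`), sum(tr$comparison == "X>Y"))
  expect_equal(s$large_inversion_total, sum(inv$size_class == "large"))
  # empty input gives an all-zero table
  s0 <- summarize_rearrangements(inv[0, ], tr[0, ])
  expect_equal(nrow(s0$counts), 0)
})
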