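# brassicomp

Comparative subgenomics of *Brassica* A genomes anchored on dense genetic
linkage maps.

The three parallel A subgenomes of *Brassica rapa* (A^r), *B. napus* (A^n)
and *B. juncea* (A^j) are strongly collinear but differ by inversions,
translocations and ancestral-block turnover. Studying them requires a
pipeline that runs from raw genotyping-by-sequencing markers to called
rearrangement events and population-genetic trees:

1. **Genetic map QC** — marker filtering (call rate > 90%, Q > 2.0 for
   SNPs, missing-rate caps of 10%/5%), classification of co-segregating
   markers into *bin loci* (connected components of missing-tolerant
   pairwise compatibility), chi-square segregation-distortion tests
   (3:1 / 1:2:1 F2 ratios), per-linkage-group map summaries, and the map
   resolution model: the shortest resolvable distance in an F2 of n
   individuals is 100/n cM (0.6 cM at n = 168).
2. **Ancestral-block synteny** — filtering of BLAST outfmt-6 alignments
   (E ≤ 1e-6 / > 40 bp for block assignment; E ≤ 1e-20 / ≥ 60 bp for
   genome comparison), assignment of mapped loci to the 24 conserved
   Brassicaceae ancestral karyotype blocks A–X by ordered criteria
   (adjacency, co-bin support, match length, E-value, identity), and
   run-based calls: ≥ 3 consecutive same-block loci form a synteny block,
   1–2 loci at ~100% identity a small insertion.
3. **Rearrangements** — inversions as strictly decreasing rank runs of
   anchors between two coordinate systems (called above 0.6 cM, small up
   to 1.2 cM genetic or 1 Mb physical), genome-pair translocations as runs
   of more than four successive genes aligning off the resident
   chromosome, map-based translocation candidates from 100%-unique hits of
   one locus or adjacent loci onto ≥ 2 chromosomes, confirmed by seeded
   neighbour-perturbation, and Table-style `total(small)` summaries.
4. **Population genetics** — allele/band-state frequencies, Nei (1972)
   standard genetic distance D = −ln(J_xy / √(J_x·J_y)), UPGMA trees with
   Newick output, polymorphism rates, and Evanno ΔK from external
   STRUCTURE-style run likelihoods.
5. **Synthetic data** — seed-deterministic simulators with planted truth:
   F2 gametes under the Haldane map function r = (1 − e^(−2d/100))/2,
   rearranged genome anchor sets, and Balding–Nichols structured panels.

See `vignettes/brassicomp-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

Simulate a small F2, recover bin loci, and call an inversion:

```r
library(brassicomp)

spec <- data.frame(marker_id = sprintf("M%02d", 1:8), lg = "A01",
                   pos_cm = c(0, 0, 4.8, 9.1, 9.1, 9.1, 15.2, 22))
sim <- simulate_f2(spec, n = 168, seed = 42, missing_rate = 0.03)
bin_loci(classify_bins(sim$calls), sim$calls)
#>   bin_id representative_id n_members is_bin_locus
#> 1    M01               M01         2         TRUE
#> 2    M03               M03         1        FALSE
#> 3    M04               M06         3         TRUE
#> 4    M07               M07         1        FALSE
#> 5    M08               M08         1        FALSE
```

The markers planted at 0 cM and at 9.1 cM co-segregate and collapse into
two bin loci; the representative is the member with the least missing data.

```r
rm168 <- resolution_model(168, genome_size_mb = 485, map_length_cm = 828.4)
rm168
#> Resolution model: n = 168, min distance 0.6 cM (small <= 1.2 cM)
#>   physical scale: 0.585 Mb/cM

anch <- data.frame(id = paste0("a", 1:5), chrom_a = "A10",
                   coord_a = 0:4, chrom_b = "A10",
                   coord_b = c(0, 3, 2, 1, 4) * 1e6)
detect_inversions(anch, rm168, unit = "genetic", comparison = "Aj-Ar")
#>   comparison chrom start_a end_a span_a n_anchors size_class anchor_ids
#> 1      Aj-Ar   A10       1     3      2         3      large   a2,a3,a4
```

Three anchors in reversed physical order over 2.0 cM — above the 1.2 cM
small/large boundary — yield one large inversion.

```r
p <- simulate_panel(K = 3, F_div = 0.3, L = 1000, n_per_pop = 3, seed = 7)
f <- allele_freqs(p$calls, p$accessions$population)
round(nei_dist_matrix(f$freq), 3)
#>       pop1  pop2  pop3
#> pop1 0.000 0.213 0.214
#> pop2 0.213 0.000 0.199
#> pop3 0.214 0.199 0.000
upgma(nei_dist_matrix(f$freq))$newick
#> "(pop1:0.107,(pop2:0.099,pop3:0.099):0.008);"  (branch lengths abridged)
```

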