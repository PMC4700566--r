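---
title: "Comparative subgenomics from dense genetic maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative subgenomics from dense genetic maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brassicomp)
```

# The problem

Allotetraploid *Brassica juncea* (A^j^A^j^B^j^B^j^) carries an A subgenome
parallel to those of *B. rapa* (A^r^) and *B. napus* (A^n^). Comparing these
three A subgenomes requires anchoring a dense genetic linkage map - built
from an F2 cross genotyped with 69-bp genotyping-by-sequencing tags - onto
physical reference genomes, expressing both in terms of the 24 conserved
Brassicaceae ancestral karyotype blocks (labelled A-X), and then calling
chromosome rearrangements and population-genetic relationships from the
anchored coordinates. `brassicomp` implements that pipeline as composable,
testable functions, together with simulators that generate every input with
planted ground truth.

# Marker quality control and bin loci

Genotyping-by-sequencing markers are retained when their call rate is
strictly above 0.90, their Q score (the log of the minimum FDR at which the
call is significant) is strictly above 2.0 for SNP markers, and their
missing-data fraction is at most 10% in a mapping population or 5% in a
diversity panel ([qc_profile()], [filter_markers()]). The strict/inclusive
readings follow the conventional phrasing of these thresholds; both are
configurable.

In an F2 of n individuals, recombination is observed at most 2n times per
interval, so markers separated by no observed recombination collapse onto
one map position. [classify_bins()] formalizes "no observed recombination"
as missing-tolerant pairwise compatibility - no individual at which both
calls are non-missing and disagree - and takes connected components of the
compatibility graph. This is a deterministic, oracle-checkable equivalent of
what interactive mapping software does internally; the test suite checks it
against a brute-force O(m^2 n) transitive closure on random fixtures. The
bin representative is the member with the least missing data, ties broken
lexicographically by id so that the choice is reproducible.

Segregation distortion is tested per marker with a Pearson chi-square
against the Mendelian F2 ratio (3:1 for dominant presence/absence, 1:2:1
for codominant markers), with no multiple-testing correction - the
conventional practice for map QC, where the flag is a data-quality signal
rather than an inference. Distorted markers are flagged, not removed;
`distortion_scan(..., drop = TRUE)` reproduces the stricter practice of
excluding them before final ordering. Locus order and cM positions are
taken as given from the input map: re-estimating them is the mapping
software's job and out of scope here.

# Map resolution

With n = 168 F2 individuals, the shortest resolvable genetic distance under
the one-centiMorgan criterion is 100/168 = 0.6 cM ([resolution_model()]).
Twice that distance (1.2 cM) bounds the "small" rearrangement class. A
physical-scale equivalent can be attached via a genome size and map length;
for a 485 Mb A subgenome over an 828.4 cM map this gives 0.585 Mb/cM, so
the conventional 1 Mb "small" physical bound is more conservative than a
naive conversion of 0.6 cM (about 0.35 Mb). We keep the two thresholds
independent - 0.6/1.2 cM in genetic units, 1 Mb in physical units - rather
than forcing them through one conversion factor, and both are exposed as
parameters.

# Ancestral-block assignment and synteny calling

Tabular alignments (BLAST outfmt-6 compatible) are filtered at two preset
stringencies: E <= 1e-6 with match length over 40 bp (strict) for
ancestral-block assignment, and E <= 1e-20 with length >= 60 bp (inclusive)
for whole-genome comparison - the asymmetry in boundary handling mirrors
the different phrasings these thresholds are usually given, and both are
configurable. A hit is intersected with block intervals by its midpoint:
blocks are megabase-scale and the 69-bp hits are points at that scale, so
midpoint assignment avoids boundary double-counting. Block coordinate
definitions are user-supplied (BED-like TSV, 0-based half-open on disk); a
bundled synthetic example encodes the 24-label schema with toy coordinates
for tests, since reference block coordinates are a curated external
resource, not something this package derives.

A locus with several candidate blocks is resolved by ordered criteria, the
first that discriminates winning: agreement with both flanking assigned
loci; support from the most co-bin member markers; longest match; smallest
E-value; highest identity. Assignment runs twice, the second pass
re-checking adjacency against provisional assignments. Ties that survive
all criteria leave the locus unassigned and flagged - inventing a label
would contaminate the downstream run statistics.

Runs of at least three consecutive same-block loci are synteny blocks; runs
of one or two loci whose supporting hits are at nearly perfect identity
(default floor 99%, configurable) are small insertions; other short runs
yield no call. Unassigned loci are transparent to runs by default because
in real data only a minority of mapped loci align to the reference (815 of
3329 in the motivating study); `strict = TRUE` makes them break runs
instead.

# Rearrangement detection

Inversions are detected as rank reversals: anchors sorted by map (or source
genome) coordinate are ranked by their partner coordinate, with co-located
anchors (one bin) sharing a rank so that a run must change rank to count.
Every maximal strictly decreasing rank run of two or more anchors is a
candidate; in genetic units it is called only when its span exceeds the map
resolution (0.6 cM), with small/large split at 1.2 cM; in physical units
any reversal is callable and 1 Mb splits the classes. A decreasing run
covering the whole chromosome is an orientation flip of the assembly, not
an inversion, and is reported separately. Non-monotone tangles are simply
not part of any strictly decreasing run, matching the practice of leaving
"too complicated" clusters uncalled rather than guessing.

Genome-to-genome translocations require more than four - that is, at least
five by the strict reading, with `min_run` exposed for the inclusive one -
successive adjacent gene anchors aligning to a chromosome different from
the source chromosome's resident (modal) partner. Map-to-genome candidates
arise when markers of one locus or two adjacent loci hit two or more
distinct target chromosomes, each with a unique 100%-identity alignment.
Because a candidate from a genetic map may be an ordering artefact, it is
confirmed by perturbation: loci within a window (default 2 loci) around
the candidate are randomly reordered (default 20 seeded replicates,
re-running the detector each time), and the candidate must recur in every
replicate. We permute locus order rather than re-running linkage mapping
because the mapping software and its parameters are outside the package;
the window/replicate defaults are deliberately modest and exposed.

Event tables are summarized per chromosome and comparison as
`total(small)` cells with a totals row; the large-event grand total is the
sum over comparisons of (total - small).

# Population genetics

Allele frequencies are direct counts: dosage sums over 2n non-missing
calls for codominant markers, and band-state (presence) frequencies for
dominant markers. Dominant markers are *not* converted to allele
frequencies under Hardy-Weinberg assumptions: the marker system mixes
presence/absence and SNP calls, the panels are largely self-pollinated
lines where HWE does not hold, and the band-state treatment keeps the two
marker types on one footing. This is a documented limitation: distances on
dominant markers are dissimilarities of band profiles, not estimates of
Nei's parameter on allele frequencies.

"Nei's coefficient" is implemented as Nei (1972) standard genetic distance,
D = -ln(Jxy / sqrt(Jx Jy)), with loci missing in either group excluded
from all three identity means and a `+Inf` sentinel when Jxy = 0. The
software cited in this literature offers several Nei variants; 1972 is the
default and the choice is deliberately prominent in the API name
([nei_distance()]) rather than hidden. Infinite distances block UPGMA with
an instructive error instead of being silently capped; `cap_infinite`
makes capping explicit.

UPGMA is implemented directly (proportional averaging, node height d/2,
smallest-label tie-break) so that the merge sequence is deterministic and
the tests can hold it against two independent references: a brute-force
cophenetic recomputation and `stats::hclust(method = "average")`. The
result carries an `ape` phylo tree, its Newick string, and an
hclust-compatible component for `cutree`/`cophenetic`.

Evanno's delta-K consumes replicate log-likelihoods exported from any
STRUCTURE-style program (the MCMC itself is out of scope):
deltaK(K) = mean over replicates of |L(K+1) - 2 L(K) + L(K-1)| divided by
the replicate standard deviation of L(K), defined for interior K of a
contiguous range. Replicates are paired by id across K; a zero replicate
standard deviation is an error rather than an infinity.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults emulate the motivating design.

* [simulate_f2()] draws two gametes per individual with crossovers from
  the Haldane model (r = (1 - exp(-2d/100))/2, no interference; Kosambi by
  flag). Haldane is the default because it gives a closed-form
  recombination oracle for the tests. Missingness is completely at random;
  segregation distortion is modelled as gametic selection (a disfavoured
  gamete survives with probability 1 - s), one concrete mechanism among
  several that produce distorted ratios. Markers at one position
  co-segregate exactly, planting the bin truth.
* [simulate_rearranged_genomes()] lays out evenly spaced anchors with
  uniform jitter below half the spacing (so collinearity is preserved
  exactly in the event-free case), then reverses partner order inside
  planted inversion intervals and reassigns planted runs to other
  chromosomes. Overlapping planted events are rejected.
* [simulate_panel()] uses the Balding-Nichols model - ancestral frequency
  per locus from Uniform(0.05, 0.95), population frequencies from
  Beta(p(1-F)/F, (1-p)(1-F)/F), optional admixture as membership-weighted
  frequency mixes, genotypes Binomial(2, freq) - as the minimal standard
  model matching the assumptions of the admixture analysis the pipeline
  consumes.

All generators are seed-deterministic: identical specification and seed
give identical output.

What the simulations do not emulate: sequence-level properties of 69-bp
tags (alignment ambiguity arises in real data from paralogy and repeats,
not at random), crossover interference, linkage disequilibrium decay within
populations, and genotyping error beyond MCAR missingness. Passing the
planted-truth tests therefore demonstrates correctness of the rules, not
robustness to every artefact of real data.

# Numerical choices and problem sizes

Closest-pair ties in UPGMA break on the lexicographically smallest label
pair; bin ids and representatives break ties lexicographically; rank ties
in inversion detection collapse to a shared rank. Identity comparisons
against 100% use a 1e-9 tolerance. The validation suite runs at desk
scale, chosen as the smallest sizes at which the statistical checks are
sharp: bin-oracle fixtures of 40-60 markers, recombination recovery at
n = 10,000 gametes pairs (3-binomial-SE band around the Haldane value),
UPGMA oracles at 7-8 taxa, and panel cluster recovery over 100 seeds at
K = 3, F = 0.3, L = 1000 markers, 8 accessions per population - conditions
under which UPGMA on Nei distances should separate species-like
populations essentially always.

# Known limitations

* Locus order is trusted as given; the package cannot detect ordering
  errors except through the perturbation check.
* Block assignment quality degrades with hit sparsity; with adjacency and
  bin information both absent, assignment falls back to per-hit scores.
* The map-based translocation detector reports candidates per locus or
  adjacent pair; it does not merge reciprocal events across comparisons,
  and directions are reported separately.
* Dominant-marker distances are band-state dissimilarities (see above).
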