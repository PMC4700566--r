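Package: brassicomp
Title: Comparative Subgenomics of Brassica A Genomes from Dense Genetic Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of Brassica subgenomes anchored
    on dense genotyping-by-sequencing linkage maps. Provides marker quality
    control and bin-locus classification for F2 mapping populations,
    segregation-distortion testing, filtering of tabular sequence alignments,
    assignment of mapped loci to the 24 conserved Brassicaceae ancestral
    karyotype blocks (A-X), run-based calling of synteny blocks and small
    insertions, rule-based detection of inversion and translocation events
    between genetic maps and physical genomes (and between genome pairs),
    and population-genetic analysis of diversity panels (Nei standard
    genetic distance, UPGMA trees with Newick output, Evanno delta-K model
    selection from admixture-run likelihoods). A seed-deterministic
    synthetic-data generator (Haldane F2 gametes, planted rearrangements,
    Balding-Nichols population structure) supplies fully specified inputs
    with planted truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
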