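Package: claRecomb
Title: Recombination Landscape, Haplotype Blocks and Cla-Element Insertions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of the interplay between a species-specific transposable
    element (the Cla-element of Chironomus riparius) and the recombination
    landscape of natural populations. Provides windowed aggregation of
    per-individual population-scaled recombination rates (rho) with hotspot
    classification, haplotype-block detection by the Gabriel
    confidence-interval method on D-prime (two-locus EM, grid-likelihood CI),
    distance-decay correlation of rho against the nearest insertion or block
    with bootstrap envelopes, inside/outside overlap statistics with exact
    binomial, Wilcoxon and constrained region-permutation tests (fixed
    chromosomes, fixed lengths, mutually non-overlapping placements), and
    shared/unique classification of insertion clusters across populations.
    Includes a synthetic-data generator (genome layout, rho maps, phased
    haplotypes with latent LD blocks, population-structured insertions with
    configurable placement bias) so every stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
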