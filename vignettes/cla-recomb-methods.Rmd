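---
title: "Methods: recombination landscape, haplotype blocks and Cla-element insertions"
author: "claRecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recombination landscape, haplotype blocks and Cla-element insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`claRecomb` implements a population-genomics workflow for asking whether a
transposable element's insertion sites are structured by the recombination
landscape of its host. The motivating system is the *Cla*-element of the
non-biting midge *Chironomus riparius*, a species-specific minisatellite-like
TE (120 bp consensus unit) that occurs both as monomers and as tandem
clusters, surveyed across five European populations of four individuals
each. The workflow takes three kinds of evidence and asks whether they
cohere:

1. **Windowed recombination rates.** Per-individual maps of the
   population-scaled recombination rate ρ (piecewise-constant interval
   tracks, as produced by SMC-based inference) are aggregated into
   fixed-width windows, summarized per chromosome and population, and
   screened for hotspots.
2. **Haplotype blocks.** Runs of SNPs in strong linkage disequilibrium,
   delimited by the Gabriel confidence-interval method on D′, with the
   conventional block-calling parameterization.
3. **Insertion clusters.** TE insertion loci per population, classified as
   unique or shared, compared against blocks (overlap statistics,
   constrained region-permutation test) and against ρ (distance-decay
   correlations).

A synthetic-data generator emits all three layers with known ground truth,
so every stage is testable without the original sequencing data.

# Coordinate conventions

All on-disk region tracks are BED-style: tab-separated, 0-based half-open.
In memory, regions are `GRanges` (1-based closed, the Bioconductor
convention); the conversion happens exactly once, in `readBed()` /
`writeBed()` and friends, eliminating off-by-one drift. Distances between
regions are *gaps*: zero when two regions share at least one bp, and also
zero for book-ended regions (end of one equals start of the next in
half-open terms). Nearest-feature ties resolve to the leftmost-starting
feature so results are deterministic.

# Windowed recombination rates

`windowRho()` computes, per individual, the coverage-weighted mean ρ of the
track segments falling in each window; segments straddling a window border
contribute only their in-window bp. Only complete windows are evaluated —
a trailing partial window is dropped — and complete windows with no
coverage are `NA`, excluded from all summaries rather than zero-filled.
This makes the windowing mass-conserving: the sum of window mean × covered
bp equals the sum of segment ρ × bp over the same extent (a tested
invariant, tolerance 1e-9 relative).

`summarizeRho()` reports mean, median and mean ± SE over all
(window × individual) values in scope, with SE = sample SD/√N. The sample
SD (n − 1 denominator) is used throughout: it is the convention of the R
functions in this toolchain. `classifyHotspots()` flags, per individual and
chromosome, windows whose ρ exceeds that individual's chromosome mean +
2 SD, and reports the union over individuals; the rule is scale-invariant
(multiplying a track by a positive constant changes nothing) and a
constant track yields no hotspots because the threshold is unexceedable.

Chromosomes with a predicted centromere are split by `splitArms()` into
arm 1, the centromere range, and arm 2 — the three parts partition the
chromosome — while a chromosome without a usable centromere (the shortest
chromosome, in the motivating system) is analysed whole.

# Haplotype blocks

The block caller follows the Gabriel confidence-interval method:

* **Gamete frequencies.** For phased genotypes the four two-locus gamete
  frequencies are counted directly (the phased path and direct counting
  agree to machine precision, a tested invariant). For unphased genotypes
  the standard two-locus EM is used; only the double heterozygote is
  phase-ambiguous, and the EM starts from an equal split of those
  individuals, iterating until the largest change is below 1e-10 (cap 1000
  iterations). A lone double heterozygote therefore settles at the
  symmetric fixed point (all four gametes at 0.25).
* **D′ confidence interval.** Alleles are oriented so D ≥ 0, the
  multinomial log-likelihood of the gamete counts is evaluated on the D′
  grid {0, 0.001, …, 1}, normalized to a probability mass, and the 90% CI
  is read off the cumulative mass (smallest grid value reaching 5% / 95%).
  A pair is *strong LD* when ciLow ≥ 0.65 and ciHigh ≥ 0.97, *strong
  recombination* when ciHigh < 0.90, otherwise uninformative; monomorphic
  pairs are degenerate and uninformative. The grid step and CI level are
  fixed constants of the method, configurable but not tuned.
* **Blocks.** A candidate block is a SNP span whose outermost pair is
  strong LD and whose bp span is at most `maxKb`; it is accepted when
  strong/(strong + recombination) over all classified pairs in the span is
  at least 0.90. Uninformative pairs are excluded from the denominator,
  following the method's "informative pairs" wording. Overlapping
  candidates resolve greedily, longest bp span first, ties to the
  leftmost. No additional span cap is applied to small (2–4 SNP) blocks;
  only the global `maxKb` limit holds.
* **Length filter.** Block length is the span between the outermost SNP
  positions (BP2 − BP1, the half-open width); the analysis retains blocks
  of at least 50 bp.

Exact bit-compatibility with any particular block-calling program is not
promised; the `.det`-style output schema is matched so downstream stages
are drop-in. Whether the informative-fraction denominator should include
uninformative pairs, and whether the length filter should be BP2 − BP1 or
BP2 − BP1 + 1, are genuinely underdetermined conventions; both choices
here (exclude; BP2 − BP1) are documented and consistent across the
package.

# Overlap statistics and the permutation test

`classifyOverlap()` marks a cluster *inside* when it shares at least one bp
with any block; book-ended regions share none. The exact binomial test
(null p0 = 0.5 by default, exposed as a parameter) and the two Wilcoxon
rank-sum comparisons — cluster size inside vs outside blocks, and block
length with vs without clusters — go through `stats::binom.test` and
`stats::wilcox.test`, the same machinery the surrounding field uses.

The region-permutation test is the package's own: each permutation
re-places every query uniformly at random on its *own* chromosome (fixed
chromosome), preserving its length (fixed length), with candidates redrawn
if they overlap an already-placed permuted query (mutually non-overlapping,
with a rejection budget of 10 000 attempts per element). Permuted queries
*may* overlap the fixed references — otherwise the statistic would be
degenerate. The permutation p-value is (k + 1)/(n + 1), never zero; the
Z-score is (observed − permuted mean)/permuted SD. Re-placement is uniform
over integer starts in [0, L − len], by rejection sampling rather than gap
shuffling, which realizes the fixed-length/no-overlap constraints most
directly.

Two reporting choices deserve a note:

* The default analysis randomizes the queries against fixed references.
  The headline inside/outside result this mirrors is consistent with that
  reading, and randomizing both sets is available as a variant.
* The `auto` tail picks the side of the observed deviation and reports it.
  For *level* assessments (how often does the test reject under a true
  null?) a fixed one-sided alternative must be used instead, since the
  adaptive tail doubles the nominal level by construction; the package's
  own property suites test the depletion direction (`"less"` on the
  overlap count) that the analysis question dictates.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the package emulates.

* **Genome.** Four chromosomes, the last much the shortest and carrying no
  usable centromere; centromeres centred at half the chromosome length
  with width 10% of it. Desk-scale lengths (400/350/300/150 kb) keep every
  stage fast while leaving hundreds of windows and SNPs per chromosome;
  all sizes are configurable.
* **ρ maps.** Expected ρ = baseline × centromere dip × telomeric
  elevation. The dip is multiplicative and smooth
  (factor^exp(−(x − mid)²/2σ²), σ = centromere width), reaching exactly
  the configured factor at the centromere midpoint; the telomeric
  elevation has compact support over the outer 10% of the chromosome, so
  it is exactly 1 at an interior centromere. Hotspot spikes are seeded by
  a Poisson process and shared across individuals (they are part of the
  population profile); individuals receive independent unit-mean gamma
  noise per segment. The baseline defaults to 0.0127 per bp, the global
  windowed mean of the motivating dataset; the centromere factor 0.1 and
  telomere factor 2 reproduce the qualitative centromere-depressed,
  telomere-elevated shape.
* **Haplotypes.** LD is induced by an ancestral-haplotype-pool model
  rather than a coalescent simulator: the genome is partitioned into
  latent blocks (exponential lengths), within a block every haploid genome
  copies one of a small pool of ancestral haplotypes (pool frequencies
  Dirichlet-drawn), and choices are independent across blocks. This gives
  direct control over true block boundaries — which the block-caller
  validation needs — at trivial compute cost. With a pool of two, every
  polymorphic intra-block pair has |D′| = 1, a sharp, testable signature.
  The model makes no claim to coalescent realism: its allele-frequency
  spectrum, decay of LD with distance *within* blocks, and recombination
  graph are all simplistic, so passing tests demonstrate correctness of
  the detection machinery, not performance on real genealogies.
* **Insertions.** Sharing classes are assigned to ancestral loci first
  (deterministic counts: round(n × fraction) shared-by-all and partially
  shared, the rest unique); populations inherit positions exactly, so
  shared insertions are coordinate-identical across populations, as a
  group-level insertion caller reports them. Default fractions 14/441 and
  139/441 and the truncated lognormal length law (meanlog 5.5, sdlog 0.6,
  truncated to [73, 1802] bp; the meanlog/sdlog pair is a documented
  package default fitted by eye to the census min/mean/max, not an
  estimate from data) match the observed census. Placement is uniform, or
  biased: density ∝ exp(−β·ρ(x)) (rho-coupled; β is an artifact knob, not
  a biological estimate), or uniform with block-overlapping candidates
  rejected with probability q (block-avoiding). Ancestral loci never
  overlap one another.
* **Seeding.** One RNG stream per generator layer, derived from the master
  seed by fixed offsets, so regenerating one layer never perturbs another;
  everything is reproducible from a single integer.

# Distance-decay analysis

Windows (population mean over individuals) are paired with the gap
distance to the nearest feature of the class — insertion clusters split at
500 bp into small/large, or haplotype blocks — via the same
nearest-feature machinery used everywhere. Both windows and features are
subset to the chromosome part under analysis, since each part is analysed
separately. Correlation (Pearson for insertion decay, Spearman for block
decay) is computed on the raw unbinned pairs; binning — 20 equal-count
distance bins by default — is used only for the bootstrap envelope of the
binned mean curve (100 replicates, resampling pairs with replacement).
Midpoint-to-midpoint distances would differ by at most half a window width
from gap distances; gap semantics matches the nearest-feature workflow the
analysis chains into.

A caution the synthetic experiments make visible: even under uniform
placement, the distance-to-nearest-feature field is spatially structured
(windows near chromosome ends see features on one side only), and ρ is
spatially structured too, so small spurious correlations arise. The
package's property suites therefore require the *bias* settings to be
recovered (positive r under rho-coupling in ≥90% of replicates) and the
*null* settings to stay mostly star-free, rather than asserting exact
zeroes.

# Problem sizes and statistical calibration of the test suites

The test and acceptance suites run at documented desk scales:

* Arithmetic and enumeration checks are instant (the discrete toy genome
  for the permutation engine has one chromosome of length 4, where the
  exact overlap probability is 0.5 by enumeration of the four placements).
* The permutation-test level and power suites use the generator's default
  scale — 4 chromosomes, 1.2 Mb total, 200 ancestral insertions, and a
  fixed reference track covering ~11% of the genome (150 regions of
  900 bp). The reference footprint matters: the null overlap count must be
  rich enough (mean ≈ 22 here) for the permutation p-value to attain the
  nominal level; with only a handful of expected overlaps the p-value is
  too discrete and the test is conservative by construction, which would
  say something about the sizing, not the engine. Level is measured over
  200 replicates at 500 permutations; power and q-monotonicity over 20
  replicates per setting.
* Block-caller validation uses pool-2 haplotypes on two chromosomes
  (450 kb, SNP density 1.5 per kb, 10 kb latent blocks), where ≥80% of
  detected block bp must fall inside true latent blocks.

# Known limitations

* The latent-block haplotype model tiles the whole genome, so detected
  blocks cover a large fraction of the synthetic genome — unlike a real
  landscape where strong-LD blocks may cover only a percent or two.
  Synthetic overlap counts are therefore exercised as *statistics*
  (level, power, monotonicity), never compared to census values from
  sparse real block landscapes.
* ρ maps are inputs (or simulated); no SMC inference is performed, and no
  uncertainty in ρ propagates into downstream statistics.
* The haplotype model has no mutation/recombination within latent blocks;
  block-caller performance on coalescent or real data will be worse than
  on this favourable geometry, and the validation quantifies machinery
  correctness only.
* The permutation null re-places insertions anywhere on the chromosome,
  including centromeric and otherwise atypical sequence; no mappability or
  accessibility mask exists in scope.
* Per-chromosome insertion tallies in compartmentalized form depend on the
  unquantified "flank" width around centromeres (default 5% of chromosome
  length per side) and are validated on synthetic ground truth only.
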