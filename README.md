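# claRecomb

Population-genomics analysis of the interplay between a transposable
element and the recombination landscape of its host, modelled on the
*Cla*-element of the non-biting midge *Chironomus riparius* — a
species-specific minisatellite-like TE (120 bp consensus unit) surveyed
across five European populations. The package is for researchers who have
per-individual recombination-rate maps (ρ interval tracks from SMC-based
inference), phased SNP genotypes, and per-population TE insertion calls,
and want to ask: are insertions structured by recombination?

## What it computes

* **Windowed ρ landscapes** — coverage-weighted window means of
  piecewise-constant per-individual ρ tracks (complete windows only),
  per-chromosome/per-population summaries (mean, median, mean ± SE with
  SE = s/√N), and hotspot calls: windows with ρ > chromosome mean + 2·SD
  for at least one individual, unioned across individuals.
* **Haplotype blocks** — the Gabriel confidence-interval method on D′:
  two-locus gamete frequencies (direct counting when phased, EM when
  unphased), a 90% grid-likelihood CI on D′ per SNP pair, pair classes
  strong LD (CI above 0.65/0.97) vs strong recombination (upper CI below
  0.90), and blocks = spans with a strong-LD outermost pair and
  informative fraction ≥ 0.90, resolved greedily longest-first; then a
  ≥ 50 bp length filter.
* **Inside/outside statistics** — overlap classification of clusters vs
  blocks, exact binomial test, Wilcoxon rank-sum comparisons, and a
  constrained region-permutation test: insertions re-placed uniformly on
  their own chromosome, lengths preserved, mutually non-overlapping;
  p = (k+1)/(n+1) and Z = (obs − mean)/SD over the permuted statistics.
* **Distance decay** — window ρ against gap distance to the nearest
  insertion cluster (< 500 bp and ≥ 500 bp classes separately, per
  chromosome arm/centromere part) or nearest haplotype block, with
  Pearson/Spearman correlations, significance stars, and 100-replicate
  bootstrap envelopes.
* **Sharing structure** — merging per-population insertion calls into
  clusters, unique / partially shared / shared-by-all classification, and
  compartment tallies (arms, centromere ± flank, whole short chromosome,
  unplaced).
* **Synthetic data** — a generator for genome layouts,
  centromere-depressed ρ maps with hotspots, phased haplotypes with latent
  LD blocks (ancestral-haplotype-pool model), and population-structured
  insertions with configurable placement bias (uniform, ρ-coupled,
  block-avoiding), all with ground truth and full seed determinism.

## Worked example

A fully synthetic end-to-end run (five populations of four individuals on
a four-chromosome desk-scale genome):

```r
library(claRecomb)
cfg <- simConfig(seed = 42)
res <- runPipeline(pipelineConfig(sim = cfg, nPerm = 1000, permSeed = 42,
                                  landscapeWidth = 10e3,
                                  claDecayWidth = 20e3, hbDecayWidth = 1e3))
```

Selected output (as printed by the code):

```
blocks detected: 133  retained >=50bp: 131
   scope    n     mean  median    seLow   seHigh
1   chr1  800 0.010591 0.01056 0.010288 0.010894
2   chr2  700 0.009777 0.01054 0.009558 0.009996
3   chr3  600 0.009767 0.01060 0.009532 0.010002
4   chr4  300 0.013704 0.01308 0.013542 0.013865
10 total 2400 0.010537 0.01120 0.010400 0.010674

clusters: 200  inside blocks: 133
Region permutation test
  statistic: n_overlapping, observed = 133
  permuted mean = 126.3, sd = 6.842 (n_perm = 1000)
  Z = 0.9806, one-sided p (greater) = 0.18281718

    sharedAll sharedPartial        unique     sharedAny
          3.0          31.5          65.5          34.5
```

Reading it: the ρ summary is the Table-style per-chromosome landscape
(mean window ρ around the 0.0127/bp baseline, depressed on the three
centromeric chromosomes and elevated on the short acentromeric chr4,
whose profile is telomere-dominated). 200 insertion clusters were merged
across populations; their sharing percentages (3.0 / 31.5 / 65.5)
recover the configured class fractions. Under the default *uniform*
placement the permutation test correctly finds nothing (Z ≈ 1, p ≈ 0.18):
insertions overlap blocks about as often as re-placed ones do. Note that
the synthetic LD blocks deliberately cover a large genome fraction —
overlap counts here are not comparable to a sparse real block landscape.
Re-running with `simConfig(seed = 42, placementMode = "block_avoiding",
placementQ = 0.9)` flips the permutation result to a strong deficit
(Z < −4, p at the resolution floor).

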