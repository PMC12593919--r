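# Fixture builders and independent oracles shared across test files.

# GenotypeMatrix from a phased haplotype matrix (sites x 2N alleles).
gmFromHaps <- function(haps, pos = seq_len(nrow(haps)) * 100,
                       chrom = "chr1", pops = NULL) {
  n <- ncol(haps) / 2
  ids <- paste0("s", seq_len(n))
  if (is.null(pops)) pops <- rep("p1", n)
  geno <- haps[, seq(1, ncol(haps), 2), drop = FALSE] +
    haps[, seq(2, ncol(haps), 2), drop = FALSE]
  colnames(geno) <- ids
  new("GenotypeMatrix",
      sites = data.frame(chrom = chrom, pos = pos,
                         id = paste0(chrom, ":", pos), ref = "A",
                         alt = "T", stringsAsFactors = FALSE),
      samples = data.frame(id = ids, population = pops,
                           stringsAsFactors = FALSE),
      geno = geno, haps = haps)
}

# unphased GenotypeMatrix from a dosage matrix (sites x samples)
gmFromGeno <- function(geno, pos = seq_len(nrow(geno)) * 100,
                       chrom = "chr1") {
  n <- ncol(geno)
  colnames(geno) <- paste0("s", seq_len(n))
  new("GenotypeMatrix",
      sites = data.frame(chrom = chrom, pos = pos,
                         id = paste0(chrom, ":", pos), ref = "A",
                         alt = "T", stringsAsFactors = FALSE),
      samples = data.frame(id = colnames(geno), population = "p1",
                           stringsAsFactors = FALSE),
      geno = geno, haps = NULL)
}

# a phased matrix where every haploid genome copies one of `pool` rows
hapsFromPool <- function(pool, choice) t(pool[choice, , drop = FALSE])

# exhaustive O(n*m) nearest-feature oracle on BED-style data.frames
bruteClosest <- function(qdf, fdf) {
  vapply(seq_len(nrow(qdf)), function(i) {
    j <- which(fdf$chrom == qdf$chrom[i])
    if (!length(j)) return(NA_real_)
    gaps <- pmax(0, pmax(fdf$start[j] - qdf$end[i],
                         qdf$start[i] - fdf$end[j]))
    min(gaps)
  }, numeric(1))
}

# brute-force Pearson and Spearman (explicit covariance / rank sums)
brutePearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
bruteSpearman <- function(x, y) brutePearson(rank(x), rank(y))

# detected-block bp falling inside true latent blocks
fracInTruth <- function(detected, truth) {
  ov <- sum(IRanges::width(IRanges::pintersect(
    IRanges::findOverlapPairs(detected, truth))))
  ov / sum(GenomicRanges::width(detected))
}
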