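# Haplotype pools used to build phased fixtures with known pair classes:
# two complementary haplotypes give perfect LD; independent fair draws give
# strong recombination evidence at moderate n.
perfectLdHaps <- function(m, nChrom) {
  pool <- rbind(rep(0L, m), rep(1L, m))
  hapsFromPool(pool, rep(c(1L, 2L), each = nChrom / 2))
}

test_that("site filters apply the MAF and missingness thresholds", {
  geno <- rbind(c(0L, 0L, 0L, 0L, 1L),   # maf 0.1
                c(0L, 0L, 0L, 0L, 0L),   # monomorphic
                c(1L, 1L, 0L, 0L, NA),   # 20% missing
                c(2L, 2L, 0L, 0L, 0L))   # maf 0.4
  g <- gmFromGeno(geno)
  kept <- filterSites(g, minMaf = 0.10, maxMissing = 0.05)
  expect_equal(kept@sites$pos, c(100, 400))
  expect_equal(nrow(filterSites(g, minMaf = 0, maxMissing = 1)@sites), 4L)
  expect_equal(nrow(filterSites(g, minMaf = 0.45, maxMissing = 0)@sites), 0L)
})

test_that("EM haplotype frequencies equal direct counting on phased data", {
  haps <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  g <- gmFromHaps(haps)
  f <- emHaplotypeFreqs(g, 1, 2)
  expect_identical(as.numeric(f), c(.5, 0, 0, .5))
  # random phased fixtures: phased counting vs the unphased EM route
  set.seed(31)
  for (r in 1:5) {
    hp <- matrix(rbinom(2 * 40, 1, 0.4), nrow = 2)
    gp <- gmFromHaps(hp)
    fp <- emHaplotypeFreqs(gp, 1, 2)
    # independent direct gamete count
    brute <- c(mean(hp[1, ] == 0 & hp[2, ] == 0),
               mean(hp[1, ] == 0 & hp[2, ] == 1),
               mean(hp[1, ] == 1 & hp[2, ] == 0),
               mean(hp[1, ] == 1 & hp[2, ] == 1))
    expect_identical(as.numeric(fp), brute)
    gu <- gmFromGeno(gp@geno)
    fu <- emHaplotypeFreqs(gu, 1, 2)
    # EM recovers the same margins; gamete freqs agree up to EM precision
    expect_equal(sum(fp[1:2]), sum(fu[1:2]), tolerance = 1e-9)
    expect_equal(sum(fp[c(1, 3)]), sum(fu[c(1, 3)]), tolerance = 1e-9)
  }
})

test_that("EM on a lone double heterozygote settles at the symmetric fixed point", {
  g <- gmFromGeno(matrix(c(1L, 1L), nrow = 2))
  f <- emHaplotypeFreqs(g, 1, 2)
  expect_equal(as.numeric(f), rep(0.25, 4))
  expect_equal(sum(f), 1)
})

test_that("a monomorphic second locus gives D = 0 exactly", {
  haps <- rbind(c(0L, 1L, 0L, 1L), rep(0L, 4))
  f <- emHaplotypeFreqs(gmFromHaps(haps), 1, 2)
  st <- dprimeCI(f, 4)
  expect_true(st$degenerate)
  expect_equal(st$D, 0)
  expect_equal(st$klass, "uninformative")
})

test_that("grid-likelihood CI classifies canonical pairs as the likelihood dictates", {
  # perfect LD, 200 chromosomes: mass concentrates at D' = 1
  st <- dprimeCI(c(.5, 0, 0, .5), 200)
  expect_gt(st$ciLow, 0.9)
  expect_equal(st$ciHigh, 1)
  expect_equal(st$klass, "strong_ld")
  # independent loci: upper bound collapses below the recombination cut
  st2 <- dprimeCI(c(.25, .25, .25, .25), 200)
  expect_lt(st2$ciHigh, 0.90)
  expect_equal(st2$klass, "strong_recomb")
  # four chromosomes cannot pin D' down: wide CI, uninformative
  st3 <- dprimeCI(c(.5, 0, 0, .5), 4)
  expect_lt(st3$ciLow, 0.65)
  expect_gt(st3$ciHigh - st3$ciLow, 0.5)
  expect_equal(st3$klass, "uninformative")
  # independent grid-integration oracle for the n = 4 perfect-LD CI:
  # L(d) ~ (1 + d)^4 on the discrete grid
  dgrid <- seq(0, 1, 0.001)
  mass <- cumsum((1 + dgrid)^4) / sum((1 + dgrid)^4)
  expect_equal(st3$ciLow, dgrid[which(mass >= 0.05)[1]])
  expect_equal(st3$ciHigh, dgrid[which(mass >= 0.95)[1]])
})

test_that("CI tightens monotonically with evidence", {
  f <- c(.5, 0, 0, .5)
  lo <- vapply(c(20, 200, 2000), function(n) dprimeCI(f, n)$ciLow,
               numeric(1))
  expect_true(all(diff(lo) >= 0))
})

test_that("block finding applies the Gabriel span and informative-fraction rules", {
  # three perfect-LD SNPs -> one block of three
  g <- gmFromHaps(perfectLdHaps(3, 40), pos = c(1000, 1500, 2600))
  det <- findBlocks(g)
  expect_equal(nrow(det), 1L)
  expect_equal(det$NSNPS, 3L)
  expect_equal(c(det$BP1, det$BP2), c(1000, 2600))
  expect_equal(det$SNPS, "chr1:1000;chr1:1500;chr1:2600")

  # independent fair loci -> no blocks
  set.seed(41)
  hapsR <- matrix(rbinom(4 * 200, 1, 0.5), nrow = 4)
  expect_equal(nrow(findBlocks(gmFromHaps(hapsR))), 0L)

  # two perfect-LD triplets separated by independence -> exactly two blocks
  h1 <- perfectLdHaps(3, 40)
  set.seed(42)
  shuffle <- sample(40)
  h2 <- perfectLdHaps(3, 40)[, shuffle]
  g2 <- gmFromHaps(rbind(h1, h2), pos = c(100, 200, 300, 5100, 5200, 5300))
  det2 <- findBlocks(g2)
  expect_equal(nrow(det2), 2L)
  expect_equal(det2$BP1, c(100, 5100))
  expect_equal(det2$NSNPS, c(3L, 3L))
})

test_that("blocks never span a strong-recombination outermost pair", {
  cfg <- simConfig(seed = 51, nChroms = 1, chromLengths = 120e3,
                   nPopulations = 5, haplotypePoolSize = 3,
                   snpDensity = 8e-4)
  lay <- simulateGenome(cfg)
  g <- filterSites(simulateHaplotypes(lay, cfg)$genotypes)
  det <- findBlocks(g)
  skip_if(nrow(det) == 0)
  for (r in seq_len(nrow(det))) {
    i <- which(g@sites$pos == det$BP1[r])
    j <- which(g@sites$pos == det$BP2[r])
    f <- emHaplotypeFreqs(g, i, j)
    expect_equal(dprimeCI(f, attr(f, "n"))$klass, "strong_ld")
  }
})

test_that("the block length filter keeps >= 50 bp spans (boundary and census)", {
  mk <- function(lens) data.frame(CHR = "chr1", BP1 = 1000,
                                  BP2 = 1000 + lens, KB = lens / 1000,
                                  NSNPS = 2L, SNPS = "a;b")
  expect_equal(nrow(filterBlocks(mk(49))), 0L)
  expect_equal(nrow(filterBlocks(mk(50))), 1L)
  out <- filterBlocks(mk(c(2, 49, 50, 22367)))
  expect_equal(out$BP2 - out$BP1, c(50, 22367))
  # size census: 23,453 blocks of which 9,848 are below 50 bp
  set.seed(61)
  lens <- c(sample(2:49, 9848, replace = TRUE),
            sample(50:22367, 23453 - 9848, replace = TRUE))
  expect_equal(nrow(filterBlocks(mk(lens))), 13605L)
})

test_that(".det tables round-trip and convert to half-open block ranges", {
  det <- data.frame(CHR = "chr2", BP1 = 101, BP2 = 250, KB = 0.149,
                    NSNPS = 4L, SNPS = "a;b;c;d",
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".det")
  writeDet(det, f)
  expect_equal(readDet(f), det)
  gr <- blocksToGRanges(det)
  expect_equal(grangesToBed(gr)$start, 100)
  expect_equal(grangesToBed(gr)$end, 250)
  expect_equal(GenomicRanges::width(gr), 150L)  # span 149 bp half-open
})
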