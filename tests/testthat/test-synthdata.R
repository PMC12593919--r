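smallCfg <- function(seed = 1, ...) {
  simConfig(seed = seed, nChroms = 2, chromLengths = c(200e3, 150e3),
            nPopulations = 3, nIndividualsPerPop = 2, teTotal = 50,
            teSharedFractionAll = 0.1, teSharedFractionPartial = 0.3, ...)
}

test_that("genome simulation is deterministic and honours the centromere geometry", {
  cfg <- simConfig(seed = 5, nChroms = 4, chromLengths = 1e6,
                   cenWidthFrac = 0.1)
  lay1 <- simulateGenome(cfg)
  lay2 <- simulateGenome(cfg)
  expect_identical(chromLengths(lay1), chromLengths(lay2))
  expect_identical(grangesToBed(centromeres(lay1)),
                   grangesToBed(centromeres(lay2)))
  expect_length(chromLengths(lay1), 4L)
  cen <- grangesToBed(centromeres(lay1))
  expect_equal(cen$end - cen$start, rep(1e5, nrow(cen)))
  # last chromosome has no centromere by default
  expect_false("chr4" %in% cen$chrom)
})

test_that("rho profile hits baseline x centromere factor exactly at the midpoint", {
  cfg <- smallCfg(rhoNoiseShape = Inf, hotspotRatePerMb = 0)
  lay <- simulateGenome(cfg)
  cen <- grangesToBed(centromeres(lay))
  cenMid <- (cen$start[1] + cen$end[1]) / 2
  L <- chromLengths(lay)[[cen$chrom[1]]]
  expect_identical(rhoProfile(cenMid, L, cenMid, cfg),
                   cfg@rhoBaseline * cfg@rhoCentromereFactor)
  # telomeric elevation at the chromosome end, none in the interior
  expect_equal(rhoProfile(0, L, NA, cfg),
               cfg@rhoBaseline * cfg@rhoTelomereFactor)
  expect_equal(rhoProfile(L / 2, L, NA, cfg), cfg@rhoBaseline)
  # noiseless simulated track equals the profile at segment midpoints
  tr <- simulateRho(lay, cfg)
  one <- tr[tr$individual == tr$individual[1] & tr$chrom == cen$chrom[1], ]
  expect_equal(one$rho,
               rhoProfile((one$start + one$end) / 2, L, cenMid, cfg))
})

test_that("gamma segment noise has unit mean around the noiseless profile", {
  cfg <- smallCfg(seed = 8, rhoNoiseShape = 4, hotspotRatePerMb = 0,
                  rhoSegmentBp = 100)  # ~3500 segments over two chromosomes
  lay <- simulateGenome(cfg)
  tr <- simulateRho(lay, cfg)
  cfg0 <- smallCfg(seed = 8, rhoNoiseShape = Inf, hotspotRatePerMb = 0,
                   rhoSegmentBp = 100)
  tr0 <- simulateRho(lay, cfg0)
  one <- tr$individual == tr$individual[1]
  ratio <- tr$rho[one] / tr0$rho[one]
  n <- sum(one)
  se <- sqrt(1 / cfg@rhoNoiseShape / n)  # SD of gamma(k, rate k) is 1/sqrt(k)
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("rho simulation is deterministic under a fixed seed", {
  cfg <- smallCfg(seed = 3)
  lay <- simulateGenome(cfg)
  expect_identical(simulateRho(lay, cfg), simulateRho(lay, cfg))
})

test_that("haplotype simulation induces the configured latent LD structure", {
  cfg <- smallCfg(seed = 4, haplotypePoolSize = 2, snpDensity = 5e-4,
                  blockLengthMean = 20e3)
  lay <- simulateGenome(cfg)
  hap1 <- simulateHaplotypes(lay, cfg)
  hap2 <- simulateHaplotypes(lay, cfg)
  expect_identical(hap1$genotypes@haps, hap2$genotypes@haps)
  expect_identical(grangesToBed(hap1$latentBlocks),
                   grangesToBed(hap2$latentBlocks))
  g <- hap1$genotypes
  expect_gt(nrow(g@sites), 0)
  # pool of one ancestral haplotype leaves nothing polymorphic
  cfg1 <- smallCfg(seed = 4, haplotypePoolSize = 1)
  expect_equal(nrow(simulateHaplotypes(lay, cfg1)$genotypes@sites), 0L)
  # pool of two: any intra-block polymorphic pair has |D'| = 1
  truth <- grangesToBed(hap1$latentBlocks)
  sitesPerBlock <- lapply(seq_len(nrow(truth)), function(b)
    which(g@sites$chrom == truth$chrom[b] &
            g@sites$pos > truth$start[b] &
            g@sites$pos <= truth$end[b]))
  idx <- sitesPerBlock[[which.max(lengths(sitesPerBlock))]]
  expect_gte(length(idx), 2)
  for (j in idx[-1]) {
    f <- emHaplotypeFreqs(g, idx[1], j)
    st <- dprimeCI(f, attr(f, "n"))
    expect_equal(st$Dprime, 1)
  }
})

test_that("phased VCF output round-trips through the VCF reader", {
  cfg <- smallCfg(seed = 6, snpDensity = 2e-4)
  lay <- simulateGenome(cfg)
  g <- simulateHaplotypes(lay, cfg)$genotypes
  f <- withr::local_tempfile(fileext = ".vcf")
  writePhasedVcf(g, f, chromLengths = chromLengths(lay))
  back <- readPhasedVcf(f)
  expect_identical(unname(back@haps), unname(g@haps))
  expect_equal(back@sites$pos, g@sites$pos)
  expect_equal(back@samples$population, g@samples$population)
})

test_that("insertion sharing classes are deterministic counts of the configured fractions", {
  cfg <- simConfig(seed = 10, nChroms = 2, chromLengths = c(300e3, 200e3),
                   nPopulations = 5, teTotal = 200,
                   teSharedFractionAll = 0.1,
                   teSharedFractionPartial = 0.3)
  lay <- simulateGenome(cfg)
  ins <- simulateInsertions(lay, cfg)
  expect_equal(unname(ins$groundTruth$classCounts),
               c(20, 60, 120))
  tab <- table(S4Vectors::mcols(ins$clusters)$sharing)
  expect_equal(unname(tab[c("shared_all", "shared_partial", "unique")]),
               array(c(20L, 60L, 120L)))
  # shared-by-all clusters appear coordinate-identical in every population
  allShared <- ins$clusters[S4Vectors::mcols(ins$clusters)$sharing ==
                              "shared_all"]
  for (p in names(ins$perPop))
    expect_equal(sum(IRanges::overlapsAny(allShared, ins$perPop[[p]],
                                          type = "equal")),
                 length(allShared))
  # lengths within the truncation bounds
  w <- GenomicRanges::width(ins$clusters)
  expect_true(all(w >= 73 & w <= 1802))
  expect_identical(grangesToBed(simulateInsertions(lay, cfg)$clusters),
                   grangesToBed(ins$clusters))
})

test_that("uniform placement is indistinguishable from uniform (KS) and q = 1 excludes blocks", {
  cfg <- simConfig(seed = 12, nChroms = 1, chromLengths = 1e6,
                   cenChroms = integer(), nPopulations = 3,
                   teTotal = 2000, teSharedFractionAll = 0,
                   teSharedFractionPartial = 0, teLengthMeanlog = 4.5)
  lay <- simulateGenome(cfg)
  ins <- simulateInsertions(lay, cfg)
  starts <- grangesToBed(ins$clusters)$start
  ks <- suppressWarnings(stats::ks.test(starts / 1e6, "punif"))
  expect_gt(ks$p.value, 0.01)

  cfgB <- simConfig(seed = 13, nChroms = 1, chromLengths = 200e3,
                    cenChroms = integer(), nPopulations = 3,
                    teTotal = 50, teSharedFractionAll = 0,
                    teSharedFractionPartial = 0,
                    placementMode = "block_avoiding", placementQ = 1)
  layB <- simulateGenome(cfgB)
  blk <- randomRegions(layB, 20, 800, seed = 1)
  insB <- simulateInsertions(layB, cfgB, blocks = blk)
  expect_equal(sum(IRanges::overlapsAny(insB$clusters, blk)), 0L)
})

test_that("infeasible placement fails with an error naming the constraint", {
  cfg <- simConfig(seed = 14, nChroms = 1, chromLengths = 5e3,
                   cenChroms = integer(), nPopulations = 3, teTotal = 40,
                   teSharedFractionAll = 0, teSharedFractionPartial = 0,
                   teLengthMeanlog = 7.2, teLengthSdlog = 0.1)
  lay <- simulateGenome(cfg)
  expect_error(simulateInsertions(lay, cfg), "infeasible placement")
})

test_that("sim config round-trips through YAML", {
  cfg <- smallCfg(seed = 77, placementMode = "rho_coupled")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeSimConfig(cfg, f)
  back <- readSimConfig(f)
  for (s in methods::slotNames(cfg))
    expect_equal(methods::slot(back, s), methods::slot(cfg, s),
                 info = s)
})
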