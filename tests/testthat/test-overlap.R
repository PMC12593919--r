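test_that("overlap classification counts shared-bp clusters as inside", {
  blocks <- bedToGRanges(data.frame(chrom = "c1", start = c(150, 300),
                                    end = c(400, 500)))
  clusters <- bedToGRanges(data.frame(chrom = c("c1", "c1", "c1", "c2"),
                                      start = c(100, 200, 400, 100),
                                      end = c(200, 300, 450, 200)))
  ov <- classifyOverlap(clusters, blocks)
  # partial overlap and containment are inside; book-ended is outside
  expect_equal(ov$inside, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ov$nInside + ov$nOutside, ov$nTotal)
  bookend <- bedToGRanges(data.frame(chrom = "c1", start = 100, end = 150))
  expect_false(classifyOverlap(bookend, blocks)$inside)
  expect_equal(classifyOverlap(clusters, blocks)$blockHasCluster,
               c(TRUE, TRUE))
})

test_that("the exact binomial test reproduces pmf-summation tail probabilities", {
  bt <- binomialTest(425, 433)
  expect_equal(round(bt$pointEstimate, 7), 0.9815242)
  expect_lt(bt$pValue, 2.2e-16)
  # two-sided tail by hand: k = 0 of 10 at p0 = 0.5 -> 2/1024
  bt0 <- binomialTest(0, 10, 0.5)
  expect_equal(bt0$pValue, 2 / 1024)
  expect_equal(bt0$pointEstimate, 0)
  expect_equal(binomialTest(5, 10, 0.5)$pValue, 1)
  expect_error(binomialTest(11, 10), "k <= n")
})

test_that("the Wilcoxon rank-sum wrapper is exact for small untied samples", {
  r <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$pValue, 2 / 6, tolerance = 1e-12)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$pValue, 1)
  big <- wilcoxonRankSum(stats::rnorm(30) + 1000, stats::rnorm(30))
  expect_lt(big$pValue, 0.001)
  expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
})

test_that("the permutation engine matches the exact enumeration on a toy genome", {
  # chromosome of length 4, unit query, block [0,2): uniform starts
  # {0,1,2,3} overlap the block for starts {0,1} -> P = 0.5
  lay <- genomeLayout(c(c1 = 4))
  q <- bedToGRanges(data.frame(chrom = "c1", start = 3, end = 4))
  r <- bedToGRanges(data.frame(chrom = "c1", start = 0, end = 2))
  pt <- permutationTest(q, r, lay, "n_overlapping", nPerm = 5000,
                        seed = 42)
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(mean(pt@permuted) - 0.5), 3 * se)
  # same seed, same inputs: identical permuted values
  pt2 <- permutationTest(q, r, lay, "n_overlapping", nPerm = 5000,
                         seed = 42)
  expect_identical(pt@permuted, pt2@permuted)
  # randomizing both sets: the block sits at starts {0,1,2}, and for each
  # of them a uniform unit query overlaps with probability 2/4 = 0.5
  ptB <- permutationTest(q, r, lay, "n_overlapping", nPerm = 5000,
                         seed = 43, randomize = "both")
  expect_lt(abs(mean(ptB@permuted) - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("permuted placements respect bounds, lengths and mutual exclusion", {
  lay <- genomeLayout(c(c1 = 5e3, c2 = 3e3))
  set.seed(101)
  q <- randomRegions(lay, 30, sample(50:200, 30, TRUE), seed = 3)
  # re-run the placement core across many draws and audit the constraints
  for (s in 1:20) {
    lens <- GenomicRanges::width(
      q[as.character(GenomeInfoDb::seqnames(q)) == "c1"])
    pl <- withr::with_seed(s,
      claRecomb:::placeNonOverlapping(length(lens), lens, 5e3))
    expect_true(all(pl$start >= 0))
    expect_true(all(pl$end <= 5e3))
    expect_equal(sort(pl$end - pl$start), sort(as.numeric(lens)))
    o <- order(pl$start)
    expect_true(all(pl$start[o][-1] >= pl$end[o][-length(o)]))
  }
})

test_that("degenerate permutation inputs are flagged rather than misreported", {
  lay <- genomeLayout(c(c1 = 1000))
  q <- bedToGRanges(data.frame(chrom = "c1", start = 10, end = 20))
  empty <- GenomicRanges::GRanges()
  pt <- permutationTest(q, empty, lay, "n_overlapping", nPerm = 100,
                        seed = 1)
  expect_true(is.na(pt@zScore))
  expect_equal(pt@pValue, 1)
  expect_equal(pt@observed, 0)
  # p-value can never be zero
  r <- bedToGRanges(data.frame(chrom = "c1", start = 0, end = 999))
  pt2 <- permutationTest(q, r, lay, "n_overlapping", nPerm = 200,
                         seed = 2, alternative = "less")
  expect_gte(pt2@pValue, 1 / 201)
  # infeasible: queries longer than the chromosome
  expect_error(permutationTest(
    bedToGRanges(data.frame(chrom = "c1", start = 0, end = 2000)),
    r, lay, nPerm = 10), "longer than")
})

test_that("a deficit of overlaps yields a negative Z for n_overlapping", {
  # when the observed count of queries outside references exceeds the
  # permuted mean, the overlap statistic must sit below its null mean
  lay <- genomeLayout(c(c1 = 100e3))
  # references cover the first half of the chromosome only
  refs <- bedToGRanges(data.frame(chrom = "c1",
                                  start = seq(0, 48e3, 2e3),
                                  end = seq(1e3, 49e3, 2e3)))
  # observed queries sit entirely in the reference-free half
  q <- bedToGRanges(data.frame(chrom = "c1",
                               start = seq(60e3, 70e3, 2e3),
                               end = seq(60.1e3, 70.1e3, 2e3)))
  pt <- permutationTest(q, refs, lay, "n_overlapping", nPerm = 500,
                        seed = 6)
  ptOut <- permutationTest(q, refs, lay, "n_outside", nPerm = 500,
                           seed = 6)
  expect_gt(ptOut@observed, mean(ptOut@permuted))
  expect_lt(pt@zScore, 0)
  expect_equal(pt@alternative, "less")
})
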