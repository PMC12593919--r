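oneTrack <- function(df) cbind(individual = "i1", population = "p1", df)

test_that("window means are coverage-weighted and drop incomplete windows", {
  lay <- genomeLayout(c(chr1 = 1000))
  # constant field: every window equals the constant
  tr <- oneTrack(data.frame(chrom = "chr1", start = seq(0, 900, 100),
                            end = seq(100, 1000, 100), rho = 0.01))
  expect_equal(windowRho(tr, lay, 250)$rho, rep(0.01, 4))
  # equal halves
  tr2 <- oneTrack(data.frame(chrom = "chr1", start = c(0, 500),
                             end = c(500, 1000), rho = c(0.02, 0)))
  expect_equal(windowRho(tr2, lay, 1000)$rho, 0.01)
  # weighted quarters: 0.04 * 250 / 1000
  tr3 <- oneTrack(data.frame(chrom = "chr1", start = c(0, 250),
                             end = c(250, 1000), rho = c(0.04, 0)))
  expect_equal(windowRho(tr3, lay, 1000)$rho, 0.01)
  # incomplete trailing window dropped; uncovered complete window is NA
  lay2 <- genomeLayout(c(chr1 = 2500))
  w <- windowRho(tr3, lay2, 1000)
  expect_equal(nrow(w), 2L)
  expect_true(is.na(w$rho[2]))
})

test_that("windowed rho conserves mass and nests across widths", {
  set.seed(71)
  lay <- genomeLayout(c(chr1 = 50e3, chr2 = 37e3))
  mkTrack <- function(ind) {
    segs <- do.call(rbind, lapply(names(chromLengths(lay)), function(ch) {
      L <- chromLengths(lay)[[ch]]
      cuts <- sort(sample(seq(100, L - 100, by = 100),
                          sample(20:40, 1)))
      data.frame(chrom = ch, start = c(0, cuts), end = c(cuts, L),
                 rho = stats::rgamma(length(cuts) + 1, 2, 100))
    }))
    cbind(individual = ind, population = "p1", segs)
  }
  tr <- mkTrack("i1")
  for (width in c(1000, 10e3)) {
    w <- windowRho(tr, lay, width)
    w <- w[!is.na(w$rho), ]
    # mass restricted to complete windows, per chromosome
    for (ch in unique(w$chrom)) {
      ww <- w[w$chrom == ch, ]
      lim <- max(ww$end)
      seg <- tr[tr$chrom == ch, ]
      clip <- pmin(seg$end, lim) - pmax(seg$start, 0)
      mass <- sum(seg$rho * pmax(clip, 0))
      expect_equal(sum(ww$rho * (ww$end - ww$start)), mass,
                   tolerance = 1e-9)
    }
  }
  # 1 kb windows block-averaged in tens equal direct 10 kb windows
  w1 <- windowRho(tr, lay, 1000)
  w10 <- windowRho(tr, lay, 10e3)
  for (ch in unique(w10$chrom)) {
    fine <- w1$rho[w1$chrom == ch]
    coarse <- w10$rho[w10$chrom == ch]
    n10 <- length(coarse)
    agg <- vapply(seq_len(n10), function(k)
      mean(fine[((k - 1) * 10 + 1):(k * 10)]), numeric(1))
    expect_equal(coarse, agg, tolerance = 1e-12)
  }
})

test_that("rho summaries report mean, median and mean +/- SE", {
  lay <- genomeLayout(c(chr1 = 3000))
  tr <- oneTrack(data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                            end = c(1000, 2000, 3000), rho = c(1, 2, 3)))
  s <- summarizeRho(windowRho(tr, lay, 1000), "total")
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$mean - s$seLow, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$seHigh - s$mean, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n, 3L)
  # all-equal values: zero-width interval
  trc <- oneTrack(data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                             end = c(1000, 2000, 3000), rho = 5))
  sc <- summarizeRho(windowRho(trc, lay, 1000), "total")
  expect_equal(c(sc$seLow, sc$seHigh), c(5, 5))
  # single value: SE undefined, warned
  lay1 <- genomeLayout(c(chr1 = 1000))
  expect_warning(s1 <- summarizeRho(windowRho(trc, lay1, 1000), "total"),
                 "single")
  expect_equal(c(s1$seLow, s1$mean, s1$seHigh), c(5, 5, 5))
})

test_that("hotspot rule flags exactly the constructed outlier", {
  lay <- genomeLayout(c(chr1 = 101e3))
  rho <- c(rep(1, 100), 50)
  tr <- oneTrack(data.frame(chrom = "chr1", start = seq(0, 100e3, 1e3),
                            end = seq(1e3, 101e3, 1e3), rho = rho))
  w <- windowRho(tr, lay, 1000)
  hs <- classifyHotspots(w)
  expect_equal(nrow(hs$perIndividual), 1L)
  expect_equal(hs$perIndividual$rho, 50)
  expect_equal(hs$perIndividual$threshold, mean(rho) + 2 * sd(rho))
  expect_equal(grangesToBed(hs$union)$start, 100e3)
  # constant track yields no hotspots
  trc <- tr; trc$rho <- 1
  expect_equal(length(classifyHotspots(windowRho(trc, lay, 1000))$union),
               0L)
})

test_that("hotspot calls are scale-invariant and unioned across individuals", {
  lay <- genomeLayout(c(chr1 = 20e3))
  set.seed(81)
  base <- data.frame(chrom = "chr1", start = seq(0, 19e3, 1e3),
                     end = seq(1e3, 20e3, 1e3),
                     rho = stats::rgamma(20, 2, 100))
  base$rho[7] <- base$rho[7] * 60
  t1 <- cbind(individual = "i1", population = "p1", base)
  t2 <- cbind(individual = "i2", population = "p1", base)
  t2$rho <- t2$rho * 1000   # pure scaling: same flags
  w <- windowRho(rbind(t1, t2), lay, 1000)
  hs <- classifyHotspots(w)
  perInd <- split(hs$perIndividual$start, hs$perIndividual$individual)
  expect_identical(perInd$i1, perInd$i2)
  # a window flagged in only one individual still enters the union
  t3 <- cbind(individual = "i3", population = "p1", base)
  t3$rho <- rep(1, 20)
  hs2 <- classifyHotspots(windowRho(rbind(t1, t3), lay, 1000))
  expect_equal(grangesToBed(hs2$union)$start, 6000)
})
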