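# Haplotype-block detection by the Gabriel confidence-interval method:
# pairwise D' with a 90% grid-likelihood CI classifies SNP pairs as strong
# LD / strong recombination / uninformative; candidate blocks are spans
# whose outermost pair is strong LD, accepted when the informative fraction
# of their internal pairs is high enough; overlaps resolve greedily,
# longest first. Parameter names and defaults mirror the conventional
# block-calling flags (max span 1000 kb, CI bounds 0.65/0.97, informative
# fraction 0.90).

#' Per-site minor allele frequency and missing rate
#'
#' @param g a [GenotypeMatrix-class].
#' @return numeric vector, one value per site.
#' @export
siteMaf <- function(g) {
  p <- rowMeans(g@geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @rdname siteMaf
#' @export
siteMissingRate <- function(g) rowMeans(is.na(g@geno))

#' Filter sites on MAF and missingness
#'
#' Retains sites with minor allele frequency >= \code{minMaf} and missing
#' fraction <= \code{maxMissing} (the conversion filter applied before
#' block calling), preserving order.
#'
#' @param g a [GenotypeMatrix-class].
#' @param minMaf minimum minor allele frequency (default 0.10).
#' @param maxMissing maximum per-site missing fraction (default 0.05).
#' @return the filtered [GenotypeMatrix-class] (possibly with zero sites).
#' @export
filterSites <- function(g, minMaf = 0.10, maxMissing = 0.05) {
  keep <- siteMaf(g) >= minMaf & siteMissingRate(g) <= maxMissing
  keep[is.na(keep)] <- FALSE
  subsetSites(g, which(keep))
}

subsetSites <- function(g, idx) {
  haps <- if (is.null(g@haps)) NULL else g@haps[idx, , drop = FALSE]
  new("GenotypeMatrix", sites = g@sites[idx, , drop = FALSE],
      samples = g@samples, geno = g@geno[idx, , drop = FALSE],
      haps = haps)
}

#' Two-locus haplotype (gamete) frequencies
#'
#' For phased input the four gamete frequencies are counted directly; for
#' unphased input they are estimated by the standard two-locus EM (only the
#' double heterozygote is phase-ambiguous), iterated from an equal-split
#' initialization until the largest frequency change is below 1e-10 or 1000
#' iterations.
#'
#' @param g a [GenotypeMatrix-class].
#' @param i,j site indices.
#' @return named numeric vector \code{c(pAB, pAb, paB, pab)} (A/a = ref/alt
#'   at site i, B/b at site j), summing to 1, with attribute \code{"n"} =
#'   number of chromosomes used.
#' @export
emHaplotypeFreqs <- function(g, i, j) {
  if (!is.null(g@haps)) {
    h1 <- g@haps[i, ]; h2 <- g@haps[j, ]
    ok <- !is.na(h1) & !is.na(h2)
    h1 <- h1[ok]; h2 <- h2[ok]
    if (!length(h1)) stop("no non-missing haplotypes for sites ", i, ", ", j)
    cnt <- c(pAB = sum(h1 == 0 & h2 == 0), pAb = sum(h1 == 0 & h2 == 1),
             paB = sum(h1 == 1 & h2 == 0), pab = sum(h1 == 1 & h2 == 1))
    f <- cnt / sum(cnt)
    attr(f, "n") <- length(h1)
    return(f)
  }
  gA <- g@geno[i, ]; gB <- g@geno[j, ]
  ok <- !is.na(gA) & !is.na(gB)
  gA <- gA[ok]; gB <- gB[ok]
  if (!length(gA)) stop("no non-missing diplotypes for sites ", i, ", ", j)
  # known gamete counts (A = ref = dosage toward 0)
  tab <- matrix(0, 3, 3)
  for (a in 0:2) for (b in 0:2) tab[a + 1, b + 1] <- sum(gA == a & gB == b)
  nDH <- tab[2, 2]
  kAB <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  kAb <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  kaB <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2]
  kab <- 2 * tab[3, 3] + tab[2, 3] + tab[3, 2]
  nChr <- 2 * length(gA)
  # equal-split initialization of the double heterozygotes
  f <- (c(kAB, kAb, kaB, kab) + nDH / 2) / nChr
  if (nDH > 0) {
    for (it in seq_len(1000L)) {
      denom <- f[1] * f[4] + f[2] * f[3]
      w <- if (denom > 0) f[1] * f[4] / denom else 0.5
      fNew <- (c(kAB + nDH * w, kAb + nDH * (1 - w),
                 kaB + nDH * (1 - w), kab + nDH * w)) / nChr
      if (max(abs(fNew - f)) < 1e-10) { f <- fNew; break }
      f <- fNew
    }
  }
  names(f) <- c("pAB", "pAb", "paB", "pab")
  attr(f, "n") <- nChr
  f
}

#' D-prime with grid-likelihood confidence interval
#'
#' Orients alleles so D >= 0, evaluates the multinomial log-likelihood of
#' the gamete counts over the D' grid \code{seq(0, 1, gridStep)}, normalizes
#' it to a probability mass, and reads the 90% CI off the cumulative mass
#' (smallest grid value reaching 5% / 95%). Classification: strong LD when
#' \code{ciLow >= strongLowCI} and \code{ciHigh >= strongHighCI}; strong
#' recombination when \code{ciHigh < recombHighCI}; otherwise
#' uninformative. A monomorphic locus yields an uninformative result with
#' \code{degenerate = TRUE} and NA bounds.
#'
#' @param freqs gamete frequencies as from [emHaplotypeFreqs()].
#' @param nChrom number of chromosomes behind the frequencies (>= 2).
#' @param strongLowCI,strongHighCI,recombHighCI classification thresholds.
#' @param gridStep D' grid resolution (default 0.001).
#' @return list with D, Dprime, ciLow, ciHigh, klass, degenerate.
#' @export
dprimeCI <- function(freqs, nChrom, strongLowCI = 0.65,
                     strongHighCI = 0.97, recombHighCI = 0.90,
                     gridStep = 0.001) {
  stopifnot(nChrom >= 2)
  cnt <- round(freqs * nChrom)
  res <- pairLdClassify(matrix(cnt, nrow = 1),
                        strongLowCI = strongLowCI,
                        strongHighCI = strongHighCI,
                        recombHighCI = recombHighCI, gridStep = gridStep)
  lapply(res, `[[`, 1L)
}

# Vectorized grid-likelihood classification. counts: matrix with columns
# (nAB, nAb, naB, nab), one row per pair. Returns parallel vectors/lists.
pairLdClassify <- function(counts, strongLowCI = 0.65, strongHighCI = 0.97,
                           recombHighCI = 0.90, gridStep = 0.001,
                           chunk = 2000L) {
  nP <- nrow(counts)
  n <- rowSums(counts)
  pA <- (counts[, 1] + counts[, 2]) / n   # freq of allele A at locus 1
  pB <- (counts[, 1] + counts[, 3]) / n
  D <- counts[, 1] / n - pA * pB
  D0 <- D
  # orient so D >= 0 by swapping the alleles of locus 2 where needed
  flip <- !is.na(D) & D < 0
  counts[flip, ] <- counts[flip, c(2, 1, 4, 3), drop = FALSE]
  pB[flip] <- 1 - pB[flip]
  Dor <- abs(D)
  Dmax <- pmin(pA * (1 - pB), (1 - pA) * pB)
  degenerate <- !is.finite(Dmax) | Dmax <= 0 |
    pA <= 0 | pA >= 1 | pB <= 0 | pB >= 1
  dgrid <- seq(0, 1, by = gridStep)
  G <- length(dgrid)
  ciLow <- rep(NA_real_, nP); ciHigh <- rep(NA_real_, nP)
  todo <- which(!degenerate)
  for (grp in split(todo, ceiling(seq_along(todo) / chunk))) {
    k <- length(grp)
    dm <- Dmax[grp]
    base11 <- pA[grp] * pB[grp]
    base10 <- pA[grp] * (1 - pB[grp])
    base01 <- (1 - pA[grp]) * pB[grp]
    base00 <- (1 - pA[grp]) * (1 - pB[grp])
    step <- dm %o% dgrid
    eps <- 1e-12
    ll <- counts[grp, 1] * log(pmax(base11 + step, eps)) +
      counts[grp, 2] * log(pmax(base10 - step, eps)) +
      counts[grp, 3] * log(pmax(base01 - step, eps)) +
      counts[grp, 4] * log(pmax(base00 + step, eps))
    w <- exp(ll - apply(ll, 1L, max))
    cum <- t(apply(w, 1L, cumsum))
    tot <- cum[, G]
    ciLow[grp] <- dgrid[rowSums(cum < 0.05 * tot) + 1L]
    ciHigh[grp] <- dgrid[rowSums(cum < 0.95 * tot) + 1L]
  }
  klass <- rep("uninformative", nP)
  klass[!degenerate & ciLow >= strongLowCI & ciHigh >= strongHighCI] <-
    "strong_ld"
  klass[!degenerate & ciHigh < recombHighCI] <- "strong_recomb"
  list(D = D0,
       Dprime = ifelse(degenerate, NA_real_, Dor / Dmax),
       ciLow = ciLow, ciHigh = ciHigh, klass = klass,
       degenerate = degenerate)
}

# Gamete counts for all phased pairs of sites on one chromosome within
# maxBp. Returns list(pairs = two-column index matrix, counts = 4-column
# count matrix). Requires complete (non-missing) haplotypes.
phasedPairCounts <- function(haps, pos, maxBp) {
  m <- nrow(haps)
  A <- haps == 0L        # allele A indicator
  C_AA <- tcrossprod(A * 1)          # both A
  C_Aa <- tcrossprod(A * 1, (!A) * 1)
  C_aA <- t(C_Aa)
  C_aa <- tcrossprod((!A) * 1)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  span <- pos[idx[, 2]] - pos[idx[, 1]]
  keep <- span <= maxBp
  idx <- idx[keep, , drop = FALSE]
  lin <- (idx[, 2] - 1L) * m + idx[, 1]
  counts <- cbind(C_AA[lin], C_Aa[lin], C_aA[lin], C_aa[lin])
  list(pairs = idx, counts = counts)
}

#' Find haplotype blocks (Gabriel CI method)
#'
#' Classifies every SNP pair within \code{maxKb} via the grid-likelihood D'
#' CI, then: a candidate block is a SNP span whose outermost pair is strong
#' LD; it is accepted when, over all classified pairs in the span,
#' \code{strong / (strong + recomb) >= informFrac} (uninformative pairs do
#' not enter the denominator). Overlapping candidates resolve greedily,
#' longest span in bp first, ties to the leftmost. Sites should first be
#' filtered with [filterSites()] (the block caller applies
#' \code{minMaf} itself as a safeguard). Phased genotypes use direct gamete
#' counting; unphased genotypes fall back to the per-pair EM.
#'
#' @param g a [GenotypeMatrix-class], sites sorted by position within
#'   chromosome.
#' @param maxKb maximum block span in kb (default 1000).
#' @param minMaf minimum MAF for sites entering the scan (default 0.10).
#' @param strongLowCI,strongHighCI,recombHighCI,informFrac Gabriel
#'   parameters (defaults 0.65, 0.97, 0.90, 0.90).
#' @param gridStep D' grid resolution.
#' @return data.frame in .det layout: CHR, BP1, BP2, KB, NSNPS, SNPS
#'   (semicolon-joined site ids), one row per block, ordered by (CHR, BP1).
#'   \code{KB} is the span \code{(BP2 - BP1)/1000} under the half-open
#'   length convention used throughout.
#' @export
findBlocks <- function(g, maxKb = 1000, minMaf = 0.10,
                       strongLowCI = 0.65, strongHighCI = 0.97,
                       recombHighCI = 0.90, informFrac = 0.90,
                       gridStep = 0.001) {
  g <- filterSites(g, minMaf = minMaf, maxMissing = 1)
  maxBp <- maxKb * 1000
  out <- list()
  for (ch in unique(g@sites$chrom)) {
    idx <- which(g@sites$chrom == ch)
    if (length(idx) < 2L) next
    pos <- g@sites$pos[idx]
    stopifnot(!is.unsorted(pos))
    if (!is.null(g@haps) && !anyNA(g@haps[idx, ])) {
      pc <- phasedPairCounts(g@haps[idx, , drop = FALSE], pos, maxBp)
    } else {
      pr <- which(upper.tri(matrix(0, length(idx), length(idx))),
                  arr.ind = TRUE)
      pr <- pr[pos[pr[, 2]] - pos[pr[, 1]] <= maxBp, , drop = FALSE]
      counts <- t(apply(pr, 1L, function(p) {
        f <- emHaplotypeFreqs(g, idx[p[1]], idx[p[2]])
        round(f * attr(f, "n"))
      }))
      pc <- list(pairs = pr, counts = counts)
    }
    if (!nrow(pc$pairs)) next
    cl <- pairLdClassify(pc$counts, strongLowCI = strongLowCI,
                         strongHighCI = strongHighCI,
                         recombHighCI = recombHighCI, gridStep = gridStep)
    m <- length(idx)
    S <- matrix(0, m, m); R <- matrix(0, m, m)
    isS <- cl$klass == "strong_ld"; isR <- cl$klass == "strong_recomb"
    S[pc$pairs[isS, , drop = FALSE]] <- 1
    S[pc$pairs[isS, c(2, 1), drop = FALSE]] <- 1
    R[pc$pairs[isR, , drop = FALSE]] <- 1
    R[pc$pairs[isR, c(2, 1), drop = FALSE]] <- 1
    CS <- apply(apply(S, 2L, cumsum), 1L, cumsum)  # CS[j, i] transposed
    CR <- apply(apply(R, 2L, cumsum), 1L, cumsum)
    subSum <- function(C, i, j) {
      tot <- C[j, j]
      if (i > 1L) tot <- tot - 2 * C[i - 1L, j] + C[i - 1L, i - 1L]
      tot / 2
    }
    cand <- pc$pairs[isS, , drop = FALSE]
    if (!nrow(cand)) next
    nStrong <- numeric(nrow(cand)); nRecomb <- numeric(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      nStrong[k] <- subSum(CS, cand[k, 1], cand[k, 2])
      nRecomb[k] <- subSum(CR, cand[k, 1], cand[k, 2])
    }
    ok <- nStrong / (nStrong + nRecomb) >= informFrac
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    spanBp <- pos[cand[, 2]] - pos[cand[, 1]]
    ord <- order(-spanBp, pos[cand[, 1]], cand[, 1])
    used <- logical(m)
    acc <- list()
    for (k in ord) {
      i1 <- cand[k, 1]; i2 <- cand[k, 2]
      if (any(used[i1:i2])) next
      used[i1:i2] <- TRUE
      acc[[length(acc) + 1L]] <- c(i1, i2)
    }
    if (!length(acc)) next
    accM <- do.call(rbind, acc)
    out[[ch]] <- data.frame(
      CHR = ch, BP1 = pos[accM[, 1]], BP2 = pos[accM[, 2]],
      KB = (pos[accM[, 2]] - pos[accM[, 1]]) / 1000,
      NSNPS = accM[, 2] - accM[, 1] + 1L,
      SNPS = vapply(seq_len(nrow(accM)), function(r)
        paste(g@sites$id[idx[accM[r, 1]:accM[r, 2]]], collapse = ";"), ""),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(CHR = character(), BP1 = numeric(), BP2 = numeric(),
                      KB = numeric(), NSNPS = integer(),
                      SNPS = character(), stringsAsFactors = FALSE))
  det <- do.call(rbind, out)
  det <- det[order(det$CHR, det$BP1), ]
  rownames(det) <- NULL
  det
}

#' Apply the minimum block-length filter
#'
#' Keeps blocks whose span \code{BP2 - BP1} is at least \code{minLenBp}
#' (default 50 bp), the refinement applied before the overlap statistics.
#'
#' @param blocks a .det-style data.frame from [findBlocks()].
#' @param minLenBp minimum length in bp.
#' @return the filtered data.frame.
#' @export
filterBlocks <- function(blocks, minLenBp = 50) {
  blocks[blocks$BP2 - blocks$BP1 >= minLenBp, , drop = FALSE]
}

#' Convert a block table to GRanges / write and read the .det dialect
#'
#' Block intervals are \code{[BP1 - 1, BP2)} in half-open terms, i.e. the
#' span between the outermost SNP positions.
#'
#' @param blocks a .det-style data.frame.
#' @return [blocksToGRanges()]: a [GRanges]; the I/O helpers return the
#'   path / the data.frame.
#' @export
blocksToGRanges <- function(blocks) {
  bedToGRanges(data.frame(chrom = blocks$CHR, start = blocks$BP1 - 1,
                          end = blocks$BP2, nsnps = blocks$NSNPS,
                          stringsAsFactors = FALSE))
}

#' @rdname blocksToGRanges
#' @param path file path.
#' @export
writeDet <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname blocksToGRanges
#' @export
readDet <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(CHR = "character", SNPS = "character"),
                    stringsAsFactors = FALSE)
}
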