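# Inside/outside statistics of insertion clusters versus haplotype blocks:
# overlap classification plus the exact binomial and Wilcoxon tests (via
# stats::), and helpers shared with the permutation test.

#' Classify clusters as inside or outside blocks
#'
#' A cluster is inside when it shares at least one bp with any block
#' (containment is a special case of overlap); book-ended intervals share
#' no bp and count as outside. The symmetric per-block flag records which
#' blocks carry at least one cluster.
#'
#' @param clusters,blocks [GRanges].
#' @return list with \code{inside} (logical per cluster), \code{nInside},
#'   \code{nOutside}, \code{nTotal}, and \code{blockHasCluster} (logical
#'   per block).
#' @export
classifyOverlap <- function(clusters, blocks) {
  inside <- IRanges::overlapsAny(clusters, blocks)
  list(inside = inside, nInside = sum(inside),
       nOutside = sum(!inside), nTotal = length(clusters),
       blockHasCluster = IRanges::overlapsAny(blocks, clusters))
}

#' Exact binomial test for inside/outside bias
#'
#' Thin wrapper around \code{stats::binom.test} reporting the point
#' estimate k/n (the "success probability") alongside the exact two-sided
#' (or one-sided) p-value.
#'
#' @param k successes (e.g. clusters outside blocks).
#' @param n trials (total clusters).
#' @param p0 null success probability (default 0.5).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list with k, n, pointEstimate, p0, pValue.
#' @examples
#' binomialTest(425, 433)$pointEstimate  # 0.9815242
#' @export
binomialTest <- function(k, n, p0 = 0.5, alternative = "two.sided") {
  stopifnot(n >= 1, k >= 0, k <= n)
  bt <- stats::binom.test(k, n, p = p0, alternative = alternative)
  list(k = k, n = n, pointEstimate = k / n, p0 = p0,
       pValue = bt$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Wrapper around \code{stats::wilcox.test}: exact for small samples
#' without ties, normal approximation with continuity and tie correction
#' otherwise. Used for (a) cluster size inside vs outside blocks and (b)
#' block length with vs without clusters.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with statistic (W), pValue, exact (logical).
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) + length(y) <= 50 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       exact = exact)
}
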