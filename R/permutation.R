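# Constrained region-permutation test: each permutation re-places every
# query uniformly at random on its own chromosome (fixed chromosome, fixed
# length, permuted queries mutually non-overlapping; they may overlap the
# fixed references, otherwise the statistic would be degenerate), and the
# overlap statistic is recomputed against the fixed references. The null
# distribution of permuted statistics gives the Z-score and the permutation
# p-value (k+1)/(n+1).

# number of queries overlapping >= 1 reference; refs pre-sorted with cummax
countOverlapping <- function(qs, qe, refs) {
  if (is.null(refs)) return(0L)
  idx <- findInterval(qe - 0.5, refs$start)  # refs with start < qe
  hit <- idx > 0L & refs$maxEnd[pmax(idx, 1L)] > qs
  sum(hit)
}

#' Region permutation test for overlap enrichment or depletion
#'
#' @param queries [GRanges] of the re-placed features (e.g. insertion
#'   clusters).
#' @param references [GRanges] of the fixed features (e.g. haplotype
#'   blocks).
#' @param layout a [GenomeLayout-class] covering every query chromosome.
#' @param statistic "n_overlapping" (queries sharing >= 1 bp with a
#'   reference) or "n_outside" (its complement).
#' @param nPerm number of permutations (default 5000).
#' @param seed optional RNG seed; same seed, same inputs give identical
#'   permuted values.
#' @param alternative "less", "greater", or "auto" (tail of the observed
#'   deviation from the permuted mean, reported as such).
#' @param randomize "queries" (default) re-places only the queries against
#'   fixed references; "both" also re-places the references (independently,
#'   under the same constraints) in every permutation.
#' @param budget rejection-sampling attempts allowed per element before an
#'   infeasibility error.
#' @return A [PermutationResult-class]. With no references (or zero
#'   permuted spread) the Z-score is NA and p = 1, flagged degenerate.
#' @examples
#' lay <- genomeLayout(c(c1 = 1000))
#' q <- randomRegions(lay, 5, 20, seed = 1)
#' r <- randomRegions(lay, 3, 50, seed = 2)
#' permutationTest(q, r, lay, nPerm = 99, seed = 3)
#' @export
permutationTest <- function(queries, references, layout,
                            statistic = c("n_overlapping", "n_outside"),
                            nPerm = 5000, seed = NULL,
                            alternative = c("auto", "less", "greater"),
                            randomize = c("queries", "both"),
                            budget = 10000L) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  randomize <- match.arg(randomize)
  if (nPerm < 1) stop("nPerm must be >= 1")
  len <- chromLengths(layout)
  qdf <- grangesToBed(queries)
  if (!all(qdf$chrom %in% names(len)))
    stop("query chromosome missing from layout: ",
         setdiff(qdf$chrom, names(len))[1])
  if (any(qdf$end - qdf$start > len[qdf$chrom]))
    stop("query longer than its chromosome")
  rdf <- grangesToBed(references)
  refByChrom <- lapply(split(rdf, rdf$chrom), function(d) {
    d <- d[order(d$start), ]
    list(start = d$start, maxEnd = cummax(d$end))
  })
  chroms <- unique(qdf$chrom)
  qByChrom <- lapply(split(qdf, qdf$chrom),
                     function(d) d$end - d$start)  # lengths per chrom

  obsOv <- 0L
  for (ch in chroms) {
    d <- qdf[qdf$chrom == ch, ]
    obsOv <- obsOv + countOverlapping(d$start, d$end, refByChrom[[ch]])
  }
  nQ <- nrow(qdf)
  observed <- if (statistic == "n_overlapping") obsOv else nQ - obsOv

  rByChrom <- lapply(split(rdf, rdf$chrom),
                     function(d) d$end - d$start)
  permuted <- withSeed(seed, {
    vapply(seq_len(nPerm), function(p) {
      refs <- refByChrom
      if (randomize == "both") {
        for (ch in names(rByChrom)) {
          rl <- rByChrom[[ch]]
          if (!ch %in% names(len))
            stop("reference chromosome missing from layout: ", ch)
          rp <- placeNonOverlapping(length(rl), rl, len[[ch]],
                                    budget = budget,
                                    what = paste0("permuted reference on ",
                                                  ch))
          o <- order(rp$start)
          refs[[ch]] <- list(start = rp$start[o],
                             maxEnd = cummax(rp$end[o]))
        }
      }
      ov <- 0L
      for (ch in chroms) {
        lens <- qByChrom[[ch]]
        pl <- placeNonOverlapping(length(lens), lens, len[[ch]],
                                  budget = budget,
                                  what = paste0("permuted query on ", ch))
        ov <- ov + countOverlapping(pl$start, pl$end, refs[[ch]])
      }
      if (statistic == "n_overlapping") ov else nQ - ov
    }, numeric(1))
  })

  mu <- mean(permuted)
  sdv <- stats::sd(permuted)
  degenerate <- !is.finite(sdv) || sdv == 0
  z <- if (degenerate) NA_real_ else (observed - mu) / sdv
  if (alternative == "auto")
    alternative <- if (observed >= mu) "greater" else "less"
  p <- if (degenerate && observed == mu) 1
  else if (alternative == "greater")
    (sum(permuted >= observed) + 1) / (nPerm + 1)
  else (sum(permuted <= observed) + 1) / (nPerm + 1)
  new("PermutationResult", statistic = statistic,
      observed = as.numeric(observed), permuted = as.numeric(permuted),
      zScore = z, pValue = min(p, 1), alternative = alternative,
      nPerm = nPerm, seed = as.numeric(seed %||% NA_real_))
}
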