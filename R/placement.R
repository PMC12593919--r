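# Shared uniform-placement core: draw non-overlapping intervals of fixed
# lengths on one chromosome, by rejection sampling over integer start
# positions in [0, L - len]. Used by the insertion simulator, the region
# permutation test and randomRegions().

# draw(len) must return one 0-based integer start; screen(s, e), if given,
# returns TRUE to accept a candidate before the mutual-overlap check.
placeNonOverlapping <- function(n, lens, L, draw = NULL, screen = NULL,
                                budget = 10000L, what = "element") {
  if (is.null(draw))
    draw <- function(len) floor(stats::runif(1L, 0, L - len + 1))
  ps <- numeric(n); pe <- numeric(n)
  k <- 0L
  for (j in seq_len(n)) {
    if (lens[j] > L)
      stop("infeasible placement: ", what, " of length ", lens[j],
           " exceeds chromosome length ", L)
    att <- 0L
    repeat {
      att <- att + 1L
      if (att > budget)
        stop("infeasible placement: rejection budget (", budget,
             ") exhausted for ", what, " (length ", lens[j],
             ", chromosome length ", L, ")")
      s <- draw(lens[j]); e <- s + lens[j]
      if (!is.null(screen) && !screen(s, e)) next
      if (k == 0L || !any(s < pe[seq_len(k)] & e > ps[seq_len(k)])) break
    }
    k <- k + 1L
    ps[k] <- s; pe[k] <- e
  }
  data.frame(start = ps, end = pe)
}

#' Draw random non-overlapping regions on a genome
#'
#' Places \code{n} regions of the given lengths uniformly at random
#' (integer starts, lengths preserved, mutually non-overlapping), each on a
#' chromosome drawn with probability proportional to its length. Useful for
#' constructing synthetic reference tracks with a known genomic footprint.
#'
#' @param layout a [GenomeLayout-class].
#' @param n number of regions.
#' @param lengths region lengths in bp (recycled to n).
#' @param seed optional seed for reproducibility.
#' @return [GRanges] of the placed regions.
#' @export
randomRegions <- function(layout, n, lengths, seed = NULL) {
  lengths <- rep_len(lengths, n)
  len <- chromLengths(layout)
  withSeed(seed, {
    chrom <- sample(names(len), n, replace = TRUE,
                    prob = len / sum(len))
    out <- lapply(names(len), function(ch) {
      i <- which(chrom == ch)
      if (!length(i)) return(NULL)
      df <- placeNonOverlapping(length(i), lengths[i], len[[ch]],
                                what = "region")
      data.frame(chrom = ch, start = df$start, end = df$end)
    })
    bedToGRanges(do.call(rbind, out[!vapply(out, is.null, TRUE)]))
  })
}
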