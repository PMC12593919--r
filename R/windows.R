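#' Tile a genome into complete fixed-width windows
#'
#' Emits the non-overlapping tiling \code{[0,w), [w,2w), ...} per chromosome.
#' Only complete windows are produced: a trailing partial window is dropped,
#' so a chromosome shorter than the width contributes no windows.
#'
#' @param layout a [GenomeLayout-class].
#' @param width window width in bp (> 0).
#' @return [GRanges] of windows, ordered by (chromosome, start).
#' @examples
#' makeWindows(genomeLayout(c(chr1 = 25)), 10)  # [0,10) and [10,20)
#' @export
makeWindows <- function(layout, width) {
  stopifnot(width > 0)
  len <- chromLengths(layout)
  n <- floor(len / width)
  if (sum(n) < 1) return(GenomicRanges::GRanges())
  chrom <- rep(names(len), n)
  starts <- unlist(lapply(n, function(k) (seq_len(k) - 1) * width),
                   use.names = FALSE)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(starts + 1, starts + width))
}

#' Distance to the nearest feature, per query
#'
#' bedtools-closest style nearest-feature search restricted to the query's
#' own chromosome. Distance is 0 when query and feature share at least one
#' bp, otherwise the gap between their nearest edges (book-ended intervals
#' have distance 0 under the half-open gap convention used throughout).
#' Equidistant ties resolve to the leftmost-starting feature. Queries on
#' chromosomes without any feature get \code{featureIndex = NA} and
#' \code{distance = NA}.
#'
#' @param queries,features [GRanges].
#' @return data.frame with columns queryIndex, featureIndex, distance.
#' @examples
#' q <- bedToGRanges(data.frame(chrom = "c1", start = 100, end = 200))
#' f <- bedToGRanges(data.frame(chrom = "c1", start = 250, end = 260))
#' closestDistance(q, f)$distance  # 50
#' @export
closestDistance <- function(queries, features) {
  nq <- length(queries)
  out <- data.frame(queryIndex = seq_len(nq),
                    featureIndex = rep(NA_integer_, nq),
                    distance = rep(NA_real_, nq))
  if (!nq || !length(features)) return(out)
  qdf <- grangesToBed(queries)   # 0-based half-open arithmetic
  fdf <- grangesToBed(features)
  for (ch in unique(qdf$chrom)) {
    qi <- which(qdf$chrom == ch)
    fi <- which(fdf$chrom == ch)
    if (!length(fi)) next
    fs <- fdf$start[fi]; fe <- fdf$end[fi]
    # left candidate: largest end <= query start, leftmost start on end ties
    ordE <- order(fe, fs)
    feS <- fe[ordE]
    leftPick <- vapply(unique(feS), function(e)
      ordE[which(feS == e)[1L]], integer(1))
    leftEnds <- unique(feS)
    # right candidate: smallest start >= query end (first in start order)
    ordS <- order(fs, fe)
    fsS <- fs[ordS]
    for (q in qi) {
      qs <- qdf$start[q]; qe <- qdf$end[q]
      ovl <- which(fs < qe & fe > qs)
      if (length(ovl)) {
        best <- ovl[order(fs[ovl], fe[ovl])][1L]
        out$featureIndex[q] <- fi[best]
        out$distance[q] <- 0
        next
      }
      li <- findInterval(qs, leftEnds)
      dl <- if (li >= 1L) qs - leftEnds[li] else Inf
      ri <- findInterval(qe - 0.5, fsS) + 1L
      dr <- if (ri <= length(fsS)) fsS[ri] - qe else Inf
      # on a distance tie the left candidate starts further left
      best <- if (dl <= dr) leftPick[li] else ordS[ri]
      out$featureIndex[q] <- fi[best]
      out$distance[q] <- min(dl, dr)
    }
  }
  out
}
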