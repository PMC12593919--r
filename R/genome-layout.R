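#' Construct a GenomeLayout
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param centromeres optional [GRanges] (or NULL) with at most one
#'   centromere range per chromosome.
#' @return A [GenomeLayout-class] object.
#' @examples
#' layout <- genomeLayout(c(chr1 = 100), centromeres = bedToGRanges(
#'   data.frame(chrom = "chr1", start = 40, end = 60)))
#' chromLengths(layout)
#' @export
genomeLayout <- function(chromLengths, centromeres = NULL) {
  if (is.null(centromeres)) centromeres <- GenomicRanges::GRanges()
  new("GenomeLayout", chromLengths = chromLengths, centromeres = centromeres)
}

#' @rdname genomeLayout
#' @param x a GenomeLayout.
#' @export
chromLengths <- function(x) x@chromLengths

#' @rdname genomeLayout
#' @export
centromeres <- function(x) x@centromeres

#' Read chromosome sizes from a two-column TSV (chrom, length)
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$length, tab$chrom)
}

#' @rdname readChromSizes
#' @param chromLengths named lengths, as from [readChromSizes()].
#' @param centromerePath optional BED3 file of centromere ranges.
#' @export
readGenomeLayout <- function(path, centromerePath = NULL,
                             chromLengths = NULL) {
  if (is.null(chromLengths)) chromLengths <- readChromSizes(path)
  cen <- if (is.null(centromerePath)) NULL else readBed(centromerePath)
  genomeLayout(chromLengths, cen)
}

#' Split a chromosome into arms and a centromere part
#'
#' Partitions a chromosome into \code{[0, cen.start)}, the centromere range,
#' and \code{[cen.end, length)}. A chromosome without a defined centromere is
#' returned as a single whole-chromosome part (the treatment the analysis
#' applies to the shortest chromosome). Parts always partition the
#' chromosome; a centromere touching a telomere yields an empty arm, dropped
#' with a warning.
#'
#' @param layout a [GenomeLayout-class].
#' @param chrom chromosome name.
#' @return [GRanges] of parts with metadata column \code{part} in
#'   \code{c("arm1", "centromere", "arm2")} or \code{"whole"}.
#' @export
splitArms <- function(layout, chrom) {
  stopifnot(chrom %in% names(chromLengths(layout)))
  L <- chromLengths(layout)[[chrom]]
  cen <- centromeres(layout)
  cen <- cen[as.character(GenomeInfoDb::seqnames(cen)) == chrom]
  if (!length(cen)) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, L))
    S4Vectors::mcols(gr)$part <- "whole"
    return(gr)
  }
  cs <- GenomicRanges::start(cen)
  ce <- GenomicRanges::end(cen)
  starts <- c(1L, cs, ce + 1L)
  ends <- c(cs - 1L, ce, L)
  parts <- c("arm1", "centromere", "arm2")
  keep <- starts <= ends
  if (!all(keep)) {
    warning("centromere touches a telomere on ", chrom,
            "; empty arm dropped")
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(starts[keep], ends[keep]))
  S4Vectors::mcols(gr)$part <- parts[keep]
  gr
}
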