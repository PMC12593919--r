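#' Simulate a genome layout
#'
#' Builds a [GenomeLayout-class] from a [SimConfig-class]: \code{nChroms}
#' chromosomes named \code{chr1..chrN} with the configured lengths, and a
#' centromere range on every chromosome listed in \code{cenChroms}, centred
#' at \code{cenPosition} with width \code{cenWidthFrac * length}. Fully
#' deterministic (no randomness is involved at this layer).
#'
#' @param config a [SimConfig-class].
#' @return A [GenomeLayout-class].
#' @examples
#' simulateGenome(simConfig(nChroms = 4))
#' @export
simulateGenome <- function(config) {
  len <- stats::setNames(config@chromLengths,
                         paste0("chr", seq_len(config@nChroms)))
  cenIdx <- intersect(config@cenChroms, seq_len(config@nChroms))
  cen <- NULL
  if (length(cenIdx)) {
    L <- len[cenIdx]
    w <- round(L * config@cenWidthFrac)
    s0 <- round(L * config@cenPosition - w / 2)  # 0-based start
    s0 <- pmax(0, pmin(s0, L - w))
    cen <- bedToGRanges(data.frame(chrom = names(len)[cenIdx],
                                   start = s0, end = s0 + w))
  }
  genomeLayout(len, cen)
}
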