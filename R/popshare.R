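# Shared/unique classification of insertion clusters across populations and
# compartment tallies (arms, centromere + flanks, whole short chromosome,
# unplaced).

#' Merge per-population insertion calls into clusters
#'
#' Insertions from different populations whose intervals overlap (share >=
#' 1 bp, or lie within \code{matchToleranceBp} of one another) are unified
#' into one cluster spanning their union, carrying the union of population
#' labels. Sharing classes: \code{unique} (one population),
#' \code{shared_partial} (more than one, fewer than all),
#' \code{shared_all}. Idempotent: merging the merged output with itself
#' changes nothing.
#'
#' @param perPop named list (population -> [GRanges] of insertion calls).
#' @param matchToleranceBp merge tolerance in bp (default 0 = require
#'   overlap).
#' @param nPopulations total number of populations surveyed (defaults to
#'   \code{length(perPop)}), used to distinguish shared_partial from
#'   shared_all.
#' @return [GRanges] of clusters with metadata columns \code{populations}
#'   (comma-joined), \code{nPopulations}, \code{sharing}, \code{lengthBp}.
#' @export
mergePopulationCalls <- function(perPop, matchToleranceBp = 0,
                                 nPopulations = length(perPop)) {
  stopifnot(length(perPop) >= 1)
  # per-population calls may carry disjoint chromosome sets
  all <- suppressWarnings(do.call(c, lapply(names(perPop), function(p) {
    gr <- perPop[[p]]
    S4Vectors::mcols(gr) <- NULL
    S4Vectors::mcols(gr)$population <- rep(p, length(gr))
    gr
  })))
  # tolerance 0: merge only truly overlapping calls (adjacent calls share
  # no bp); tolerance t > 0: also merge calls separated by a gap <= t
  gapw <- if (matchToleranceBp > 0) matchToleranceBp + 1L else 0L
  maxg <- if (matchToleranceBp > 0) matchToleranceBp else -1L
  merged <- GenomicRanges::reduce(all, min.gapwidth = gapw,
                                  ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(merged, all, maxgap = maxg)
  popList <- split(S4Vectors::mcols(all)$population[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
  pops <- vapply(seq_along(merged), function(i) {
    p <- sort(unique(popList[[as.character(i)]]))
    paste(p, collapse = ",")
  }, "")
  nP <- lengths(strsplit(pops, ","))
  S4Vectors::mcols(merged)$populations <- pops
  S4Vectors::mcols(merged)$nPopulations <- nP
  S4Vectors::mcols(merged)$sharing <-
    ifelse(nP == 1L, "unique",
           ifelse(nP >= nPopulations, "shared_all", "shared_partial"))
  S4Vectors::mcols(merged)$lengthBp <- GenomicRanges::width(merged)
  merged
}

#' Tally clusters by sharing class and genomic compartment
#'
#' Each cluster is assigned to exactly one compartment: centromere +/- the
#' configured flank takes precedence over the arms; a chromosome without a
#' centromere counts as one whole-chromosome compartment; clusters on
#' chromosomes absent from the layout go to \code{unplaced}. The
#' cross-tabulation collapses sharing to shared (> 1 population) vs unique.
#'
#' @param clusters [GRanges] from [mergePopulationCalls()] (needs a
#'   \code{sharing} metadata column).
#' @param layout a [GenomeLayout-class].
#' @param centromereFlankFrac flank width on each side of the centromere,
#'   as a fraction of chromosome length (default 0.05).
#' @return list with \code{byClass} (named counts unique / shared_partial /
#'   shared_all), \code{byCompartment} (data.frame compartment x
#'   shared/unique), \code{total}.
#' @export
tallySharing <- function(clusters, layout, centromereFlankFrac = 0.05) {
  sharing <- S4Vectors::mcols(clusters)$sharing
  stopifnot(!is.null(sharing))
  len <- chromLengths(layout)
  cen <- centromeres(layout)
  cdf <- grangesToBed(clusters)
  comp <- rep("unplaced", nrow(cdf))
  known <- cdf$chrom %in% names(len)
  for (ch in names(len)) {
    i <- which(cdf$chrom == ch)
    if (!length(i)) next
    cc <- cen[as.character(GenomeInfoDb::seqnames(cen)) == ch]
    if (!length(cc)) { comp[i] <- paste0(ch, ":whole"); next }
    flank <- centromereFlankFrac * len[[ch]]
    cs <- GenomicRanges::start(cc) - 1 - flank
    ce <- GenomicRanges::end(cc) + flank
    inCen <- cdf$start[i] < ce & cdf$end[i] > cs
    comp[i][inCen] <- paste0(ch, ":centromere")
    mid <- (cdf$start[i] + cdf$end[i]) / 2
    comp[i][!inCen & mid < cs] <- paste0(ch, ":arm1")
    comp[i][!inCen & mid >= cs] <- paste0(ch, ":arm2")
  }
  sharedFlag <- ifelse(sharing == "unique", "unique", "shared")
  byClass <- table(factor(sharing, levels = c("shared_all",
                                              "shared_partial", "unique")))
  byComp <- as.data.frame.matrix(table(comp, sharedFlag))
  list(byClass = c(byClass), byCompartment = byComp,
       total = length(clusters))
}

#' Sharing percentages (one decimal, half-up)
#'
#' Percentage of clusters shared by all populations, shared partially,
#' unique, and shared by any (>= 2 populations), each of the total,
#' rounded half-up to one decimal.
#'
#' @param counts named numeric with elements shared_all, shared_partial,
#'   unique (as from \code{tallySharing()$byClass}).
#' @return named numeric: sharedAll, sharedPartial, unique, sharedAny.
#' @examples
#' sharingPercentages(c(shared_all = 14, shared_partial = 139,
#'                      unique = 288))
#' @export
sharingPercentages <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("total cluster count must be positive")
  pc <- function(x) roundHalfUp(100 * x / total, 1L)
  c(sharedAll = pc(counts[["shared_all"]]),
    sharedPartial = pc(counts[["shared_partial"]]),
    unique = pc(counts[["unique"]]),
    sharedAny = pc(counts[["shared_all"]] + counts[["shared_partial"]]))
}
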