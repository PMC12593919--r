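# Synthetic population-structured TE insertions. Sharing classes are
# assigned to ancestral insertion loci first; populations then inherit
# positions exactly, mirroring how a group-level insertion caller names
# shared sites (shared insertions are coordinate-identical across
# populations).

#' Simulate TE insertions across populations
#'
#' Ancestral loci are split deterministically into sharing classes
#' (\code{round(teTotal * fraction)} shared-by-all and partially shared, the
#' remainder unique); a partially shared locus goes to a uniform random
#' subset of at least two (and fewer than all) populations, a unique locus
#' to one random population. Lengths follow the truncated lognormal
#' configured in the [SimConfig-class]. Placement start positions are drawn
#' uniformly per chromosome (chromosomes weighted by length), with density
#' proportional to \code{exp(-beta * rho(x))} in \code{rho_coupled} mode
#' (rho from the mean of the supplied tracks), or uniformly with candidates
#' overlapping a block rejected with probability \code{q} in
#' \code{block_avoiding} mode. Ancestral loci never overlap one another;
#' an exhausted rejection budget raises an error naming the constraint.
#' Deterministic given \code{config@seed}.
#'
#' @param layout a [GenomeLayout-class].
#' @param config a [SimConfig-class]; \code{config@placementMode} selects
#'   the bias model.
#' @param rhoTracks rho track data.frame (required for
#'   \code{rho_coupled}).
#' @param blocks [GRanges] of block ranges (required for
#'   \code{block_avoiding}).
#' @return list with elements \code{clusters} (a [GRanges] of ancestral
#'   loci with metadata columns \code{insertionId}, \code{lengthBp},
#'   \code{populations} (comma-joined), \code{sharing}), \code{perPop}
#'   (named list of per-population [GRanges]), and \code{groundTruth}
#'   (placement mode, parameters and the per-insertion sharing classes).
#' @export
simulateInsertions <- function(layout, config, rhoTracks = NULL,
                               blocks = NULL) {
  mode <- config@placementMode
  if (mode == "rho_coupled" && is.null(rhoTracks))
    stop("rho_coupled placement needs rhoTracks")
  if (mode == "block_avoiding" && is.null(blocks))
    stop("block_avoiding placement needs blocks")
  len <- chromLengths(layout)
  P <- config@nPopulations
  pops <- paste0("pop", seq_len(P))
  n <- config@teTotal
  nAll <- round(n * config@teSharedFractionAll)
  nPartial <- round(n * config@teSharedFractionPartial)
  if (nPartial > 0L && P < 3L)
    stop("partial sharing needs at least 3 populations")
  nUnique <- n - nAll - nPartial
  sharing <- rep(c("shared_all", "shared_partial", "unique"),
                 c(nAll, nPartial, nUnique))

  # mean-rho segment weights for rho_coupled mode
  segW <- NULL
  if (mode == "rho_coupled") {
    agg <- stats::aggregate(rho ~ chrom + start + end, data = rhoTracks,
                            FUN = mean)
    agg <- agg[order(agg$chrom, agg$start), ]
    segW <- split(agg, agg$chrom)
  }
  blockByChrom <- NULL
  if (mode == "block_avoiding") {
    bdf <- grangesToBed(blocks)
    blockByChrom <- split(bdf, bdf$chrom)
  }

  withSeed(deriveSeed(config@seed, 5L), {
    popSets <- lapply(sharing, function(cl) {
      switch(cl,
             shared_all = pops,
             shared_partial = sort(sample(pops,
                                          sample(seq(2L, P - 1L), 1L))),
             unique = sample(pops, 1L))
    })
    lens <- numeric(0)
    while (length(lens) < n) {
      cand <- stats::rlnorm(n, config@teLengthMeanlog, config@teLengthSdlog)
      cand <- cand[cand >= config@teLengthMin & cand <= config@teLengthMax]
      lens <- c(lens, cand)
    }
    lens <- round(lens[seq_len(n)])
    chrom <- sample(names(len), n, replace = TRUE, prob = len / sum(len))

    placed <- lapply(names(len), function(ch) {
      i <- which(chrom == ch)
      if (!length(i)) return(NULL)
      L <- len[[ch]]
      draw <- NULL; screen <- NULL
      if (mode == "rho_coupled") {
        sw <- segW[[ch]]
        w <- exp(-config@placementBeta * sw$rho) * (sw$end - sw$start)
        draw <- function(l) {
          j <- sample.int(nrow(sw), 1L, prob = w)
          s <- floor(stats::runif(1L, sw$start[j], sw$end[j]))
          min(max(s, 0), L - l)
        }
      } else if (mode == "block_avoiding") {
        bc <- blockByChrom[[ch]]
        screen <- function(s, e) {
          if (!is.null(bc) && nrow(bc) &&
              any(s < bc$end & e > bc$start))
            stats::runif(1L) >= config@placementQ
          else TRUE
        }
      }
      df <- placeNonOverlapping(length(i), lens[i], L, draw = draw,
                                screen = screen,
                                what = paste0("insertion (", mode,
                                              ") on ", ch))
      cbind(idx = i, chrom = ch, df)
    })
    placed <- do.call(rbind, placed[!vapply(placed, is.null, TRUE)])
    placed <- placed[order(placed$idx), ]

    clusters <- bedToGRanges(data.frame(
      chrom = placed$chrom, start = placed$start, end = placed$end,
      insertionId = paste0("ins", seq_len(n)),
      lengthBp = placed$end - placed$start,
      populations = vapply(popSets, paste, "", collapse = ","),
      sharing = sharing, stringsAsFactors = FALSE))
    clusters <- GenomicRanges::sort(clusters)
    perPop <- lapply(pops, function(p) {
      keep <- vapply(S4Vectors::mcols(clusters)$populations,
                     function(s) p %in% strsplit(s, ",")[[1]], TRUE)
      clusters[unname(keep)]
    })
    names(perPop) <- pops
    list(clusters = clusters, perPop = perPop,
         groundTruth = list(placementMode = mode,
                            placementBeta = config@placementBeta,
                            placementQ = config@placementQ,
                            sharing = sharing,
                            classCounts = c(shared_all = nAll,
                                            shared_partial = nPartial,
                                            unique = nUnique)))
  })
}
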