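# Synthetic recombination maps: a shared population profile (centromere dip,
# telomeric elevation, hotspot spikes) with independent per-individual
# multiplicative gamma noise on piecewise-constant segments.

#' Noise-free expected rho profile
#'
#' Closed-form expected rho at positions \code{x} (bp, 0-based) on one
#' chromosome: \code{baseline * dip(x) * telo(x)} where the centromere dip is
#' a smooth multiplicative depression reaching exactly
#' \code{rhoCentromereFactor} at the centromere midpoint
#' (\code{factor^exp(-(x-mid)^2 / (2 sigma^2))} with sigma the centromere
#' width), and the telomeric elevation has compact support over the outer 10%
#' of the chromosome (\code{1 + (teloFactor-1) (1 - d/r)^2} for distance d to
#' the nearer end, r = 0.1 L), so it is exactly 1 at an interior centromere.
#'
#' @param x positions in bp (0-based, numeric vector).
#' @param chromLength chromosome length in bp.
#' @param cenMid centromere midpoint in bp, or NA for no centromere.
#' @param config a [SimConfig-class].
#' @return numeric vector of expected rho per bp.
#' @export
rhoProfile <- function(x, chromLength, cenMid, config) {
  dip <- rep(1, length(x))
  if (!is.na(cenMid)) {
    sigma <- config@cenWidthFrac * chromLength
    dip <- config@rhoCentromereFactor ^
      exp(-((x - cenMid)^2) / (2 * sigma^2))
  }
  d <- pmin(x, chromLength - x)
  r <- 0.1 * chromLength
  telo <- ifelse(d < r,
                 1 + (config@rhoTelomereFactor - 1) * (1 - d / r)^2, 1)
  config@rhoBaseline * dip * telo
}

#' Simulate per-individual recombination maps
#'
#' Emits one piecewise-constant rho track per individual (all populations),
#' as a long data.frame with 0-based half-open segments. Each chromosome is
#' segmented into \code{rhoSegmentBp} pieces (trailing partial segment
#' kept); the shared population profile is [rhoProfile()] times
#' hotspot spikes (hotspot count Poisson with rate
#' \code{hotspotRatePerMb * L/1e6}, positions uniform, multiplicative
#' intensity over \code{hotspotWidthBp}); individuals then receive
#' independent unit-mean gamma noise per segment
#' (\code{rgamma(shape, rate = shape)}); \code{rhoNoiseShape = Inf} disables
#' noise. Deterministic given \code{config@seed}.
#'
#' @param layout a [GenomeLayout-class] (from [simulateGenome()]).
#' @param config a [SimConfig-class].
#' @return data.frame with columns individual, population, chrom, start,
#'   end, rho; and attribute \code{"hotspots"}, a [GRanges] of the true
#'   hotspot ranges.
#' @export
simulateRho <- function(layout, config) {
  len <- chromLengths(layout)
  cen <- centromeres(layout)
  cenMid <- stats::setNames(rep(NA_real_, length(len)), names(len))
  if (length(cen)) {
    cc <- as.character(GenomeInfoDb::seqnames(cen))
    cenMid[cc] <- (GenomicRanges::start(cen) - 1 +
                     GenomicRanges::end(cen)) / 2
  }
  segs <- do.call(rbind, lapply(names(len), function(ch) {
    L <- len[[ch]]
    starts <- seq(0, L - 1, by = config@rhoSegmentBp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + config@rhoSegmentBp, L))
  }))
  mid <- (segs$start + segs$end) / 2

  # shared population profile, incl. hotspot spikes
  base <- numeric(nrow(segs))
  for (ch in names(len)) {
    i <- which(segs$chrom == ch)
    base[i] <- rhoProfile(mid[i], len[[ch]], cenMid[[ch]], config)
  }
  profile <- withSeed(deriveSeed(config@seed, 2L), {
    hs <- lapply(names(len), function(ch) {
      L <- len[[ch]]
      nh <- stats::rpois(1L, config@hotspotRatePerMb * L / 1e6)
      if (!nh) return(NULL)
      ctr <- stats::runif(nh, 0, L)
      s0 <- pmax(0, round(ctr - config@hotspotWidthBp / 2))
      data.frame(chrom = ch, start = s0,
                 end = pmin(s0 + config@hotspotWidthBp, L))
    })
    hs <- do.call(rbind, hs[!vapply(hs, is.null, TRUE)])
    if (!is.null(hs) && nrow(hs)) {
      for (k in seq_len(nrow(hs))) {
        hit <- segs$chrom == hs$chrom[k] & mid >= hs$start[k] &
          mid < hs$end[k]
        base[hit] <- base[hit] * config@hotspotIntensity
      }
    }
    list(base = base, hotspots = hs)
  })

  pops <- paste0("pop", seq_len(config@nPopulations))
  inds <- unlist(lapply(pops, function(p)
    paste0(p, "_ind", seq_len(config@nIndividualsPerPop))))
  popOf <- rep(pops, each = config@nIndividualsPerPop)

  tracks <- withSeed(deriveSeed(config@seed, 3L), {
    do.call(rbind, lapply(seq_along(inds), function(j) {
      noise <- if (is.finite(config@rhoNoiseShape))
        stats::rgamma(nrow(segs), shape = config@rhoNoiseShape,
                      rate = config@rhoNoiseShape)
      else rep(1, nrow(segs))
      data.frame(individual = inds[j], population = popOf[j],
                 chrom = segs$chrom, start = segs$start, end = segs$end,
                 rho = profile$base * noise)
    }))
  })
  hsGr <- if (is.null(profile$hotspots)) GenomicRanges::GRanges()
  else bedToGRanges(profile$hotspots)
  attr(tracks, "hotspots") <- hsGr
  tracks
}

#' Read/write per-individual rho tracks as TSV
#'
#' External format: tab-separated chrom, start, end, rho (0-based
#' half-open), one file per individual, as produced by SMC-based
#' recombination-map binning tools.
#'
#' @param path TSV path (gzip supported by R's readers).
#' @param individual,population labels attached to the track.
#' @return data.frame with columns individual, population, chrom, start,
#'   end, rho.
#' @export
readRhoTrack <- function(path, individual = NA_character_,
                         population = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "rho"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  if (any(tab$rho < 0) || any(!is.finite(tab$rho)))
    stop("rho track has negative or non-finite values: ", path)
  cbind(individual = individual, population = population, tab)
}

#' @rdname readRhoTrack
#' @param track one individual's rows of a rho track data.frame.
#' @export
writeRhoTrack <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "rho")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
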