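#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats rbinom rexp rgamma rlnorm rpois runif
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenomeLayout: chromosome lengths and centromere ranges
#'
#' Container for the coordinate frame of an analysis: named chromosome
#' lengths (bp) and, optionally, one predicted centromere range per
#' chromosome. Chromosomes without a centromere (e.g. a short chromosome
#' analysed in its entirety) are allowed and handled by downstream splitting
#' as "whole-chromosome" scopes.
#'
#' @slot chromLengths named numeric vector, chromosome -> length in bp.
#' @slot centromeres [GRanges] of centromere ranges, at most one per
#'   chromosome, each within \code{[0, length)} of its chromosome
#'   (stored 1-based closed as usual for GRanges).
#' @export
setClass("GenomeLayout",
  slots = c(chromLengths = "numeric", centromeres = "GRanges"))

setValidity("GenomeLayout", function(object) {
  msgs <- character()
  len <- object@chromLengths
  if (length(len) == 0L) msgs <- c(msgs, "chromLengths must be non-empty")
  if (is.null(names(len)) || any(!nzchar(names(len))))
    msgs <- c(msgs, "chromLengths must be named by chromosome")
  if (anyDuplicated(names(len)))
    msgs <- c(msgs, "duplicated chromosome names")
  if (any(!is.finite(len)) || any(len <= 0))
    msgs <- c(msgs, "chromosome lengths must be positive and finite")
  cen <- object@centromeres
  if (length(cen)) {
    cc <- as.character(GenomeInfoDb::seqnames(cen))
    if (anyDuplicated(cc))
      msgs <- c(msgs, "at most one centromere per chromosome")
    if (!all(cc %in% names(len)))
      msgs <- c(msgs, "centromere on unknown chromosome")
    else {
      L <- len[cc]
      if (any(GenomicRanges::start(cen) < 1) ||
          any(GenomicRanges::end(cen) > L))
        msgs <- c(msgs, "centromere outside chromosome bounds")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: parameters of the synthetic-data generator
#'
#' Holds every knob of the simulator. Defaults encode the study design the
#' package emulates: 5 populations of 4 individuals, 4 chromosomes with the
#' shortest lacking a usable centromere, centromere-depressed rho landscapes
#' with hotspots, block-structured phased haplotypes, and
#' population-structured insertions whose sharing fractions and length law
#' match the observed cluster census (14/441 shared by all, 139/441 partially
#' shared; lengths 73-1802 bp, mean ~304 bp).
#'
#' @slot seed master RNG seed; all layer seeds are derived from it.
#' @slot nChroms number of chromosomes.
#' @slot chromLengths chromosome lengths in bp (recycled to nChroms).
#' @slot cenPosition relative position of the centromere midpoint.
#' @slot cenWidthFrac centromere width as a fraction of chromosome length.
#' @slot cenChroms indices of chromosomes that get a centromere (default all
#'   but the last, mirroring a short chromosome analysed whole).
#' @slot nPopulations,nIndividualsPerPop sampling design.
#' @slot snpDensity expected SNPs per bp (Poisson positions).
#' @slot blockLengthMean mean latent LD-block length in bp (exponential).
#' @slot haplotypePoolSize ancestral haplotypes per latent block.
#' @slot teTotal number of ancestral insertion loci.
#' @slot teSharedFractionAll,teSharedFractionPartial sharing-class fractions.
#' @slot teLengthMeanlog,teLengthSdlog lognormal length law parameters.
#' @slot teLengthMin,teLengthMax truncation bounds of the length law (bp).
#' @slot placementMode one of "uniform", "rho_coupled", "block_avoiding".
#' @slot placementBeta rho-coupling strength (density ~ exp(-beta * rho)).
#' @slot placementQ block-avoidance probability in [0,1].
#' @slot rhoBaseline baseline rho per bp.
#' @slot rhoCentromereFactor multiplicative rho depression at the centromere
#'   midpoint (<1 depresses).
#' @slot rhoTelomereFactor multiplicative rho elevation at chromosome ends.
#' @slot rhoSegmentBp width of the piecewise-constant rho segments.
#' @slot rhoNoiseShape gamma shape of the unit-mean per-segment noise;
#'   \code{Inf} disables noise.
#' @slot hotspotRatePerMb expected hotspots per Mb per chromosome.
#' @slot hotspotIntensity multiplicative rho spike inside a hotspot.
#' @slot hotspotWidthBp hotspot width in bp.
#' @export
setClass("SimConfig",
  slots = c(
    seed = "numeric",
    nChroms = "numeric",
    chromLengths = "numeric",
    cenPosition = "numeric",
    cenWidthFrac = "numeric",
    cenChroms = "numeric",
    nPopulations = "numeric",
    nIndividualsPerPop = "numeric",
    snpDensity = "numeric",
    blockLengthMean = "numeric",
    haplotypePoolSize = "numeric",
    teTotal = "numeric",
    teSharedFractionAll = "numeric",
    teSharedFractionPartial = "numeric",
    teLengthMeanlog = "numeric",
    teLengthSdlog = "numeric",
    teLengthMin = "numeric",
    teLengthMax = "numeric",
    placementMode = "character",
    placementBeta = "numeric",
    placementQ = "numeric",
    rhoBaseline = "numeric",
    rhoCentromereFactor = "numeric",
    rhoTelomereFactor = "numeric",
    rhoSegmentBp = "numeric",
    rhoNoiseShape = "numeric",
    hotspotRatePerMb = "numeric",
    hotspotIntensity = "numeric",
    hotspotWidthBp = "numeric"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  frac <- c(object@teSharedFractionAll, object@teSharedFractionPartial,
            object@cenPosition, object@cenWidthFrac, object@placementQ)
  if (any(frac < 0 | frac > 1))
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (object@teSharedFractionAll + object@teSharedFractionPartial > 1)
    msgs <- c(msgs, "teSharedFractionAll + teSharedFractionPartial must be <= 1")
  if (!object@placementMode %in% c("uniform", "rho_coupled", "block_avoiding"))
    msgs <- c(msgs, "unknown placementMode")
  if (object@nChroms < 1 || any(object@chromLengths <= 0))
    msgs <- c(msgs, "need >= 1 chromosome with positive lengths")
  if (object@nPopulations < 1 || object@nIndividualsPerPop < 1)
    msgs <- c(msgs, "need >= 1 population and individual")
  if (any(c(object@rhoBaseline, object@rhoSegmentBp, object@snpDensity,
            object@blockLengthMean) <= 0))
    msgs <- c(msgs, "rhoBaseline, rhoSegmentBp, snpDensity, blockLengthMean must be > 0")
  if (object@teLengthMin >= object@teLengthMax)
    msgs <- c(msgs, "teLengthMin must be < teLengthMax")
  if (length(msgs)) msgs else TRUE
})

#' GenotypeMatrix: biallelic SNP genotypes, optionally phased
#'
#' Sites x samples diploid genotype store. Phased data additionally carry a
#' sites x haplotypes 0/1 matrix (two columns per sample) from which gamete
#' frequencies are counted directly; unphased data fall back to the two-locus
#' EM.
#'
#' @slot sites data.frame with columns chrom, pos (1-based), id, ref, alt.
#' @slot samples data.frame with columns id, population.
#' @slot geno integer matrix (sites x samples) of alt-allele dosages 0/1/2,
#'   NA for missing.
#' @slot haps integer matrix (sites x 2*samples) of phased alleles 0/1, or
#'   NULL when unphased.
#' @export
setClass("GenotypeMatrix",
  slots = c(sites = "data.frame", samples = "data.frame",
            geno = "matrix", haps = "matrixOrNULL"))

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  needed <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(needed %in% names(object@sites)))
    msgs <- c(msgs, "sites needs columns chrom, pos, id, ref, alt")
  if (!all(c("id", "population") %in% names(object@samples)))
    msgs <- c(msgs, "samples needs columns id, population")
  if (nrow(object@geno) != nrow(object@sites))
    msgs <- c(msgs, "geno rows must match sites")
  if (ncol(object@geno) != nrow(object@samples))
    msgs <- c(msgs, "geno columns must match samples")
  if (!is.null(object@haps)) {
    if (nrow(object@haps) != nrow(object@sites) ||
        ncol(object@haps) != 2L * nrow(object@samples))
      msgs <- c(msgs, "haps must be sites x 2*samples")
  }
  if (length(msgs)) msgs else TRUE
})

#' PermutationResult: outcome of a constrained region-permutation test
#'
#' @slot statistic name of the overlap statistic ("n_overlapping" or
#'   "n_outside").
#' @slot observed observed value of the statistic.
#' @slot permuted numeric vector of permuted statistic values.
#' @slot zScore (observed - mean(permuted)) / sd(permuted); NA when the
#'   permuted distribution is degenerate.
#' @slot pValue (# permutations as or more extreme + 1) / (nPerm + 1).
#' @slot alternative tail actually tested ("less" or "greater").
#' @slot nPerm number of permutations.
#' @slot seed seed used for the permutations (NA if none supplied).
#' @export
setClass("PermutationResult",
  slots = c(statistic = "character", observed = "numeric",
            permuted = "numeric", zScore = "numeric", pValue = "numeric",
            alternative = "character", nPerm = "numeric", seed = "numeric"))

setValidity("PermutationResult", function(object) {
  msgs <- character()
  if (length(object@permuted) != object@nPerm)
    msgs <- c(msgs, "permuted values must have length nPerm")
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    msgs <- c(msgs, "pValue must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout with", length(object@chromLengths), "chromosomes\n")
  for (ch in names(object@chromLengths)) {
    cen <- object@centromeres[
      as.character(GenomeInfoDb::seqnames(object@centromeres)) == ch]
    cat(sprintf("  %s: %s bp%s\n", ch,
                format(object@chromLengths[[ch]], big.mark = ","),
                if (length(cen))
                  sprintf(" (centromere %s-%s)",
                          format(GenomicRanges::start(cen) - 1L,
                                 big.mark = ","),
                          format(GenomicRanges::end(cen), big.mark = ","))
                else " (no centromere)"))
  }
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d sites x %d samples (%s)\n",
              nrow(object@sites), nrow(object@samples),
              if (is.null(object@haps)) "unphased" else "phased"))
  cat("  populations:",
      paste(unique(object@samples$population), collapse = ", "), "\n")
})

setMethod("show", "PermutationResult", function(object) {
  cat("Region permutation test\n")
  cat(sprintf("  statistic: %s, observed = %g\n",
              object@statistic, object@observed))
  cat(sprintf("  permuted mean = %.4g, sd = %.4g (n_perm = %d)\n",
              mean(object@permuted), stats::sd(object@permuted),
              as.integer(object@nPerm)))
  cat(sprintf("  Z = %.4f, one-sided p (%s) = %.8g\n",
              object@zScore, object@alternative, object@pValue))
})
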