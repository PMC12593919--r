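#' Create a simulation configuration
#'
#' Returns a [SimConfig-class] with the package's study-design defaults:
#' five populations of four individuals on a four-chromosome genome whose
#' shortest chromosome carries no usable centromere; centromere-depressed
#' rho landscapes with telomeric elevation and Poisson-seeded hotspots;
#' block-structured phased haplotypes drawn from ancestral haplotype pools;
#' and population-structured insertions whose sharing fractions (14/441
#' shared by all, 139/441 partially shared) and truncated-lognormal length
#' law (73-1802 bp) match the observed cluster census. Chromosome lengths
#' default to a desk-scale genome (hundreds of kb) with relative sizes
#' mirroring a genome whose fourth chromosome is much the shortest.
#'
#' @param seed master RNG seed; each generator layer derives its own stream
#'   from it by a fixed offset, so regenerating one layer never perturbs
#'   another.
#' @param nChroms,chromLengths,cenPosition,cenWidthFrac,cenChroms genome
#'   layout parameters; see [SimConfig-class].
#' @param nPopulations,nIndividualsPerPop sampling design.
#' @param snpDensity,blockLengthMean,haplotypePoolSize haplotype generator.
#' @param teTotal,teSharedFractionAll,teSharedFractionPartial,teLengthMeanlog,teLengthSdlog,teLengthMin,teLengthMax
#'   insertion generator.
#' @param placementMode,placementBeta,placementQ insertion placement bias.
#' @param rhoBaseline,rhoCentromereFactor,rhoTelomereFactor,rhoSegmentBp,rhoNoiseShape,hotspotRatePerMb,hotspotIntensity,hotspotWidthBp
#'   rho landscape generator.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nChroms = 2, chromLengths = c(2e5, 1e5))
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 4L,
                      chromLengths = c(400e3, 350e3, 300e3, 150e3),
                      cenPosition = 0.5,
                      cenWidthFrac = 0.1,
                      cenChroms = seq_len(max(1L, nChroms - 1L)),
                      nPopulations = 5L,
                      nIndividualsPerPop = 4L,
                      snpDensity = 0.001,
                      blockLengthMean = 10e3,
                      haplotypePoolSize = 4L,
                      teTotal = 200L,
                      teSharedFractionAll = 14 / 441,
                      teSharedFractionPartial = 139 / 441,
                      teLengthMeanlog = 5.5,
                      teLengthSdlog = 0.6,
                      teLengthMin = 73,
                      teLengthMax = 1802,
                      placementMode = c("uniform", "rho_coupled",
                                        "block_avoiding"),
                      placementBeta = 300,
                      placementQ = 0.9,
                      rhoBaseline = 0.0127,
                      rhoCentromereFactor = 0.1,
                      rhoTelomereFactor = 2,
                      rhoSegmentBp = 1000,
                      rhoNoiseShape = 5,
                      hotspotRatePerMb = 2,
                      hotspotIntensity = 10,
                      hotspotWidthBp = 2000) {
  placementMode <- match.arg(placementMode)
  chromLengths <- rep_len(chromLengths, nChroms)
  new("SimConfig", seed = seed, nChroms = nChroms,
      chromLengths = chromLengths, cenPosition = cenPosition,
      cenWidthFrac = cenWidthFrac, cenChroms = cenChroms,
      nPopulations = nPopulations,
      nIndividualsPerPop = nIndividualsPerPop, snpDensity = snpDensity,
      blockLengthMean = blockLengthMean,
      haplotypePoolSize = haplotypePoolSize, teTotal = teTotal,
      teSharedFractionAll = teSharedFractionAll,
      teSharedFractionPartial = teSharedFractionPartial,
      teLengthMeanlog = teLengthMeanlog, teLengthSdlog = teLengthSdlog,
      teLengthMin = teLengthMin, teLengthMax = teLengthMax,
      placementMode = placementMode, placementBeta = placementBeta,
      placementQ = placementQ, rhoBaseline = rhoBaseline,
      rhoCentromereFactor = rhoCentromereFactor,
      rhoTelomereFactor = rhoTelomereFactor, rhoSegmentBp = rhoSegmentBp,
      rhoNoiseShape = rhoNoiseShape, hotspotRatePerMb = hotspotRatePerMb,
      hotspotIntensity = hotspotIntensity, hotspotWidthBp = hotspotWidthBp)
}

#' Read/write a SimConfig as YAML
#'
#' @param path YAML file path.
#' @return [readSimConfig()] returns a [SimConfig-class];
#'   [writeSimConfig()] invisibly returns the path.
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simConfig, vals)
}

#' @rdname readSimConfig
#' @param config a [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
  sl <- methods::slotNames(config)
  vals <- lapply(sl, function(s) methods::slot(config, s))
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}
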