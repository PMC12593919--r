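# End-to-end driver: simulate (or load) -> haplotype blocks -> windowed rho
# and hotspots -> decay correlations -> overlap + permutation statistics ->
# sharing tally, with every stage output written to the output directory.

#' Pipeline configuration
#'
#' Either a [SimConfig-class] (synthetic run) or paths to a phased VCF, rho
#' track TSVs, per-population insertion BEDs, a chromosome-sizes TSV and a
#' centromere BED. Window widths default to the analysis design: a coarse
#' landscape width for summaries/hotspots, a coarser width for insertion
#' decay and a fine width for block decay; on the desk-scale synthetic
#' genome the defaults below keep the same ordering at proportionally
#' smaller sizes.
#'
#' @param sim a [SimConfig-class], or NULL to load data from paths.
#' @param vcf,rhoTracks,insertionBeds,chromSizes,centromereBed input paths
#'   (ignored when \code{sim} is given). \code{rhoTracks} and
#'   \code{insertionBeds} are named vectors (individual -> path,
#'   population -> path).
#' @param landscapeWidth,claDecayWidth,hbDecayWidth window widths in bp.
#' @param nPerm,permSeed permutation-test settings.
#' @param minBlockLen minimum block length retained (bp).
#' @param outDir output directory (created if missing), or NULL to skip
#'   writing files.
#' @return a validated config list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(sim = NULL, vcf = NULL, rhoTracks = NULL,
                           insertionBeds = NULL, chromSizes = NULL,
                           centromereBed = NULL,
                           landscapeWidth = 10e3, claDecayWidth = 20e3,
                           hbDecayWidth = 1e3, nPerm = 5000,
                           permSeed = 1L, minBlockLen = 50,
                           outDir = NULL) {
  if (is.null(sim)) {
    needed <- list(vcf = vcf, chromSizes = chromSizes)
    for (nm in names(needed)) {
      if (is.null(needed[[nm]]))
        stop("pipeline config error: ", nm,
             " path required when not simulating")
      if (!file.exists(needed[[nm]]))
        stop("pipeline config error: ", nm, " file not found: ",
             needed[[nm]])
    }
    for (p in c(rhoTracks, insertionBeds, centromereBed))
      if (!file.exists(p))
        stop("pipeline config error: file not found: ", p)
  }
  stopifnot(landscapeWidth > 0, claDecayWidth > 0, hbDecayWidth > 0)
  structure(list(sim = sim, vcf = vcf, rhoTracks = rhoTracks,
                 insertionBeds = insertionBeds, chromSizes = chromSizes,
                 centromereBed = centromereBed,
                 landscapeWidth = landscapeWidth,
                 claDecayWidth = claDecayWidth,
                 hbDecayWidth = hbDecayWidth, nPerm = nPerm,
                 permSeed = permSeed, minBlockLen = minBlockLen,
                 outDir = outDir),
            class = "pipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Chains every stage on synthetic or user data: (1) simulate or load
#' layout, rho tracks, phased genotypes and per-population insertions; (2)
#' detect haplotype blocks and apply the length filter; (3) window rho,
#' summarize and classify hotspots; (4) insertion and block decay
#' correlations; (5) inside/outside statistics with binomial, Wilcoxon and
#' permutation tests; (6) sharing classification and tally. Deterministic
#' given the config seeds; outputs are written as TSV/BED under
#' \code{outDir} when set, along with a run log recording seeds and
#' parameters.
#'
#' @param config a config from [pipelineConfig()].
#' @return list with elements layout, blocks, blocksFiltered, rhoWindows,
#'   rhoSummary, hotspots, decay (data.frame of correlations), overlap,
#'   permutation (a [PermutationResult-class]), clusters, sharingTally,
#'   sharingPercent.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (!is.null(config$sim)) {
    sim <- config$sim
    layout <- simulateGenome(sim)
    tracks <- simulateRho(layout, sim)
    hap <- simulateHaplotypes(layout, sim)
    g <- hap$genotypes
    ins <- simulateInsertions(layout, sim, rhoTracks = tracks,
                              blocks = hap$latentBlocks)
    perPop <- ins$perPop
  } else {
    layout <- readGenomeLayout(config$chromSizes,
                               centromerePath = config$centromereBed)
    trackList <- lapply(names(config$rhoTracks), function(ind)
      readRhoTrack(config$rhoTracks[[ind]], individual = ind,
                   population = sub("_.*$", "", ind)))
    tracks <- do.call(rbind, trackList)
    g <- readPhasedVcf(config$vcf)
    perPop <- lapply(config$insertionBeds, readBed)
    names(perPop) <- names(config$insertionBeds)
  }

  gf <- filterSites(g, minMaf = 0.10, maxMissing = 0.05)
  blocks <- findBlocks(gf)
  blocksF <- filterBlocks(blocks, minLenBp = config$minBlockLen)
  blockGr <- blocksToGRanges(blocksF)

  rw <- windowRho(tracks, layout, config$landscapeWidth)
  rhoSummary <- rbind(summarizeRho(rw, "chrom"),
                      summarizeRho(rw, "population"),
                      summarizeRho(rw, "total"))
  hotspots <- classifyHotspots(rw)

  clusters <- mergePopulationCalls(perPop)
  wByPop <- split(rw, rw$population)
  fByPop <- lapply(names(wByPop), function(p) perPop[[p]])
  names(fByPop) <- names(wByPop)
  rwCla <- windowRho(tracks, layout, config$claDecayWidth)
  decayCla <- decayHeatmapTable(split(rwCla, rwCla$population), fByPop,
                                layout,
                                featureClasses = c("cla_small",
                                                   "cla_large"),
                                method = "pearson")
  rwHb <- windowRho(tracks, layout, config$hbDecayWidth)
  dsHb <- suppressMessages(buildDecay(rwHb, blockGr,
                                      featureClass = "haplotype_block"))
  decayHb <- cbind(population = "all", chrom = "all", part = "genome",
                   featureClass = "haplotype_block",
                   correlateDecay(dsHb, "spearman"))
  decay <- rbind(decayCla, decayHb)

  ov <- classifyOverlap(clusters, blockGr)
  binom <- binomialTest(ov$nOutside, ov$nTotal)
  wilcoxSize <- if (ov$nInside > 0 && ov$nOutside > 0)
    wilcoxonRankSum(GenomicRanges::width(clusters)[ov$inside],
                    GenomicRanges::width(clusters)[!ov$inside])
  else NULL
  hasCl <- ov$blockHasCluster
  wilcoxBlockLen <- if (any(hasCl) && any(!hasCl))
    wilcoxonRankSum(blocksF$BP2[hasCl] - blocksF$BP1[hasCl],
                    blocksF$BP2[!hasCl] - blocksF$BP1[!hasCl])
  else NULL
  perm <- if (length(blockGr))
    permutationTest(clusters, blockGr, layout,
                    statistic = "n_overlapping", nPerm = config$nPerm,
                    seed = config$permSeed, alternative = "auto")
  else NULL

  tally <- tallySharing(clusters, layout)
  pct <- sharingPercentages(tally$byClass)

  res <- list(layout = layout, blocks = blocks, blocksFiltered = blocksF,
              rhoWindows = rw, rhoSummary = rhoSummary,
              hotspots = hotspots, decay = decay,
              overlap = c(ov[c("nInside", "nOutside", "nTotal")],
                          list(binomial = binom, wilcoxSize = wilcoxSize,
                               wilcoxBlockLen = wilcoxBlockLen)),
              permutation = perm, clusters = clusters,
              sharingTally = tally, sharingPercent = pct)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    od <- function(f) file.path(config$outDir, f)
    writeDet(blocksF, od("blocks.det"))
    writeBed(blockGr, od("blocks.bed"))
    utils::write.table(rhoSummary, od("rho_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeBed(hotspots$union, od("hotspots.bed"))
    utils::write.table(decay, od("decay_correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeBed(clusters, od("clusters_merged.bed"))
    utils::write.table(
      data.frame(class = names(tally$byClass),
                 count = as.integer(tally$byClass)),
      od("sharing_tally.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log <- c(paste("run at:", format(Sys.time())),
             paste("permSeed:", config$permSeed),
             paste("nPerm:", config$nPerm),
             if (!is.null(config$sim))
               paste("sim master seed:", config$sim@seed),
             paste("landscapeWidth:", config$landscapeWidth),
             paste("claDecayWidth:", config$claDecayWidth),
             paste("hbDecayWidth:", config$hbDecayWidth))
    writeLines(log, od("run_log.txt"))
  }
  res
}
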