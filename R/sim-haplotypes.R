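# Synthetic phased haplotypes with controlled LD structure. LD is induced by
# an ancestral-haplotype-pool model: the genome is partitioned into latent
# blocks (exponential lengths); within a block every haploid genome copies
# one of a small pool of ancestral haplotypes (pool frequencies
# Dirichlet-drawn), and choices are independent across blocks. This gives
# exact control over true block boundaries at trivial compute cost, which is
# what the block-detection validation needs; it makes no claim to
# coalescent realism.

#' Simulate phased haplotypes with latent LD blocks
#'
#' SNP positions follow a Poisson process at \code{snpDensity}; latent block
#' boundaries follow an exponential length law with mean
#' \code{blockLengthMean}. Within a latent block each of the 2N haploid
#' genomes is a copy of one of \code{haplotypePoolSize} ancestral haplotypes
#' (allele 0/1 per site drawn fair per ancestral haplotype; pool frequencies
#' Dirichlet(1)); choices are independent across blocks. Sites monomorphic
#' in the emitted sample are dropped, so a pool of one yields no variants.
#' Deterministic given \code{config@seed}.
#'
#' @param layout a [GenomeLayout-class].
#' @param config a [SimConfig-class].
#' @return list with elements \code{genotypes} (a phased
#'   [GenotypeMatrix-class]) and \code{latentBlocks} (a [GRanges] of the
#'   true latent block ranges, ground truth for block-detection validation).
#' @export
simulateHaplotypes <- function(layout, config) {
  len <- chromLengths(layout)
  pops <- paste0("pop", seq_len(config@nPopulations))
  sampleIds <- unlist(lapply(pops, function(p)
    paste0(p, "_ind", seq_len(config@nIndividualsPerPop))))
  popOf <- rep(pops, each = config@nIndividualsPerPop)
  H <- 2L * length(sampleIds)
  K <- config@haplotypePoolSize

  out <- withSeed(deriveSeed(config@seed, 4L), {
    sites <- list(); hapRows <- list(); blocks <- list()
    for (ch in names(len)) {
      L <- len[[ch]]
      nSnp <- stats::rpois(1L, config@snpDensity * L)
      nSnp <- min(nSnp, L)
      pos <- sort(sample.int(L, nSnp))          # 1-based positions
      # latent block boundaries tile [0, L)
      bl <- stats::rexp(ceiling(3 * L / config@blockLengthMean) + 10L,
                        rate = 1 / config@blockLengthMean)
      edges <- cumsum(bl)
      edges <- c(0, edges[edges < L], L)
      blocks[[ch]] <- data.frame(chrom = ch, start = edges[-length(edges)],
                                 end = edges[-1])
      if (!nSnp) next
      blockIdx <- findInterval(pos - 1, edges, rightmost.closed = FALSE)
      hap <- matrix(0L, nrow = nSnp, ncol = H)
      for (b in unique(blockIdx)) {
        i <- which(blockIdx == b)
        pool <- matrix(stats::rbinom(K * length(i), 1L, 0.5),
                       nrow = K, ncol = length(i))
        freq <- stats::rgamma(K, shape = 1)
        choice <- sample.int(K, H, replace = TRUE, prob = freq / sum(freq))
        hap[i, ] <- t(pool[choice, , drop = FALSE])
      }
      poly <- rowSums(hap) > 0L & rowSums(hap) < H
      if (!any(poly)) next
      sites[[ch]] <- data.frame(chrom = ch, pos = pos[poly],
                                stringsAsFactors = FALSE)
      hapRows[[ch]] <- hap[poly, , drop = FALSE]
    }
    list(sites = sites, hapRows = hapRows, blocks = blocks)
  })

  blocksDf <- do.call(rbind, out$blocks)
  latent <- bedToGRanges(data.frame(chrom = blocksDf$chrom,
                                    start = floor(blocksDf$start),
                                    end = ceiling(blocksDf$end)))
  sitesDf <- if (length(out$sites)) do.call(rbind, out$sites)
  else data.frame(chrom = character(), pos = numeric())
  haps <- if (length(out$hapRows)) do.call(rbind, out$hapRows)
  else matrix(0L, 0L, H)
  sitesDf$id <- if (nrow(sitesDf))
    paste0(sitesDf$chrom, ":", sitesDf$pos) else character()
  sitesDf$ref <- rep("A", nrow(sitesDf))
  sitesDf$alt <- rep("T", nrow(sitesDf))
  rownames(sitesDf) <- NULL
  geno <- haps[, seq(1L, H, by = 2L), drop = FALSE] +
    haps[, seq(2L, H, by = 2L), drop = FALSE]
  colnames(geno) <- sampleIds
  g <- new("GenotypeMatrix", sites = sitesDf,
           samples = data.frame(id = sampleIds, population = popOf,
                                stringsAsFactors = FALSE),
           geno = geno, haps = haps)
  list(genotypes = g, latentBlocks = latent)
}
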