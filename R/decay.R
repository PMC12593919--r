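# Distance-decay analysis: window rho against distance to the nearest
# feature (insertion cluster by size class, or haplotype block), per
# chromosome part, with Pearson/Spearman correlation and a bootstrap
# envelope of the binned mean curve.

#' Build a decay dataset (distance to nearest feature vs window rho)
#'
#' Windows (population-mean rho per window unless already single-series)
#' are clipped to the genomic part; features of the requested class are
#' subset to the same part (each part is analysed separately); each window
#' is paired with the gap distance to the nearest feature via
#' [closestDistance()]. Feature size classes split at
#' \code{sizeSplitBp}: \code{cla_small} strictly below, \code{cla_large} at
#' or above. A part without any feature of the class yields an empty
#' dataset with a message.
#'
#' @param windows windowed rho data.frame (from [windowRho()]); multiple
#'   individuals are averaged per window first.
#' @param features [GRanges] of features.
#' @param part [GRanges] of one genomic scope (an element of
#'   [splitArms()] output), or NULL for the whole genome.
#' @param featureClass one of "all", "cla_small", "cla_large" (by width),
#'   or "haplotype_block" (no size split).
#' @param sizeSplitBp size-class boundary in bp (default 500).
#' @return data.frame with columns distance, rho (one row per window with a
#'   feature on its part), plus attributes \code{"featureClass"} and
#'   \code{"part"}.
#' @export
buildDecay <- function(windows, features, part = NULL,
                       featureClass = c("all", "cla_small", "cla_large",
                                        "haplotype_block"),
                       sizeSplitBp = 500) {
  featureClass <- match.arg(featureClass)
  w <- windows[!is.na(windows$rho), , drop = FALSE]
  agg <- stats::aggregate(rho ~ chrom + start + end, data = w, FUN = mean)
  if (featureClass == "cla_small")
    features <- features[GenomicRanges::width(features) < sizeSplitBp]
  else if (featureClass == "cla_large")
    features <- features[GenomicRanges::width(features) >= sizeSplitBp]
  wgr <- bedToGRanges(agg[, c("chrom", "start", "end")])
  if (!is.null(part)) {
    # windows/features and the part may live on disjoint chromosome sets
    keepW <- suppressWarnings(IRanges::overlapsAny(wgr, part))
    agg <- agg[keepW, , drop = FALSE]
    wgr <- wgr[keepW]
    features <- features[suppressWarnings(
      IRanges::overlapsAny(features, part))]
  }
  if (!length(features) || !nrow(agg)) {
    message("decay: no ", featureClass, " features (or windows) in part; ",
            "empty dataset")
    out <- data.frame(distance = numeric(), rho = numeric())
  } else {
    cd <- closestDistance(wgr, features)
    keep <- !is.na(cd$distance)
    if (any(!keep))
      message("decay: dropped ", sum(!keep),
              " windows on chromosomes without features")
    out <- data.frame(distance = cd$distance[keep], rho = agg$rho[keep])
  }
  attr(out, "featureClass") <- featureClass
  attr(out, "part") <- if (is.null(part)) "genome"
  else paste0(as.character(GenomeInfoDb::seqnames(part))[1], ":",
              S4Vectors::mcols(part)$part[1] %||% "part")
  out
}

#' Correlate rho with distance to the nearest feature
#'
#' Pearson (insertion decay) or Spearman (block decay) correlation on the
#' raw (distance, rho) pairs, via \code{stats::cor.test}. Significance
#' stars follow the usual convention (* p < 0.05, ** p < 0.01,
#' *** p < 0.001). A positive coefficient means rho increases with distance
#' to the feature.
#'
#' @param ds decay dataset from [buildDecay()].
#' @param method "pearson" or "spearman".
#' @return data.frame row with method, r, pValue, n, stars; r is NA with a
#'   zero-variance margin or n < 3.
#' @export
correlateDecay <- function(ds, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- nrow(ds)
  if (n < 3L || stats::sd(ds$distance) == 0 || stats::sd(ds$rho) == 0)
    return(data.frame(method = method, r = NA_real_, pValue = NA_real_,
                      n = n, stars = NA_character_))
  ct <- suppressWarnings(stats::cor.test(ds$distance, ds$rho,
                                         method = method, exact = FALSE))
  r <- unname(ct$estimate)
  p <- ct$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
  data.frame(method = method, r = r, pValue = p, n = n, stars = stars,
             stringsAsFactors = FALSE)
}

#' Bootstrap envelope of the binned decay curve
#'
#' Each replicate resamples the (distance, rho) pairs with replacement
#' (same n) and recomputes the mean rho per distance bin; bins are
#' equal-count (quantile) distance bins of the observed data, so the
#' envelope visualizes the sampling distribution of the binned mean curve.
#' Deterministic under a seed.
#'
#' @param ds decay dataset from [buildDecay()].
#' @param nReps number of bootstrap replicates (default 100).
#' @param bins number of equal-count distance bins (default 20).
#' @param seed optional RNG seed.
#' @return list with \code{binMid} (bin midpoints), \code{curves}
#'   (nReps x bins matrix of mean rho; NA where a replicate has no point in
#'   a bin) and \code{observed} (binned mean of the original data).
#' @export
bootstrapDecay <- function(ds, nReps = 100, bins = 20, seed = NULL) {
  stopifnot(nrow(ds) >= 2)
  bins <- min(bins, length(unique(ds$distance)))
  brk <- unique(stats::quantile(ds$distance, probs = seq(0, 1,
                                                         length.out = bins + 1)))
  cut0 <- function(d) findInterval(d, brk, rightmost.closed = TRUE,
                                   all.inside = TRUE)
  nb <- length(brk) - 1L
  obsBin <- cut0(ds$distance)
  observed <- vapply(seq_len(nb), function(b)
    mean(ds$rho[obsBin == b]), numeric(1))
  curves <- withSeed(seed, {
    t(vapply(seq_len(nReps), function(r) {
      i <- sample.int(nrow(ds), nrow(ds), replace = TRUE)
      bi <- cut0(ds$distance[i])
      vapply(seq_len(nb), function(b) {
        v <- ds$rho[i][bi == b]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    }, numeric(nb)))
  })
  list(binMid = (brk[-1] + brk[-length(brk)]) / 2, curves = curves,
       observed = observed)
}

#' Long-format correlation table for the decay heatmap
#'
#' One row per (population, chromosome, part, feature class, method)
#' combination with r, p and stars; undefined correlations appear as NA
#' rows, suitable for direct heatmap plotting.
#'
#' @param windowsByPop named list (population -> windowed rho data.frame).
#' @param featuresByPop named list (population -> feature [GRanges]).
#' @param layout a [GenomeLayout-class].
#' @param featureClasses feature classes to tabulate.
#' @param method correlation method.
#' @param sizeSplitBp size-class boundary.
#' @return long-format data.frame with columns population, chrom, part,
#'   featureClass, method, r, pValue, n, stars.
#' @export
decayHeatmapTable <- function(windowsByPop, featuresByPop, layout,
                              featureClasses = c("cla_small", "cla_large"),
                              method = "pearson", sizeSplitBp = 500) {
  rows <- list()
  for (pop in names(windowsByPop)) {
    for (ch in names(chromLengths(layout))) {
      parts <- splitArms(layout, ch)
      for (k in seq_along(parts)) {
        for (fc in featureClasses) {
          ds <- suppressMessages(
            buildDecay(windowsByPop[[pop]], featuresByPop[[pop]],
                       part = parts[k], featureClass = fc,
                       sizeSplitBp = sizeSplitBp))
          cr <- correlateDecay(ds, method = method)
          rows[[length(rows) + 1L]] <- cbind(
            population = pop, chrom = ch,
            part = S4Vectors::mcols(parts)$part[k],
            featureClass = fc, cr)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
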