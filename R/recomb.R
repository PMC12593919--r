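# Windowed aggregation of per-individual rho tracks, Table-style summaries
# (mean/median/SE per chromosome, population, or overall) and hotspot
# classification (window rho above the individual's chromosome mean + 2 SD).

#' Aggregate a rho track into fixed windows
#'
#' Window mean = coverage-weighted mean of segment rho over the window;
#' segments straddling a window border contribute only their in-window bp.
#' Only complete windows are evaluated (trailing partial windows are
#' dropped); complete windows with zero covered bp get NA and are excluded
#' from summaries.
#'
#' @param tracks rho track data.frame (columns individual, population,
#'   chrom, start, end, rho; 0-based half-open), one or many individuals.
#' @param layout a [GenomeLayout-class].
#' @param width window width in bp.
#' @return data.frame with columns individual, population, chrom, start,
#'   end (0-based half-open window), rho (weighted mean; NA if uncovered).
#' @examples
#' lay <- genomeLayout(c(chr1 = 1000))
#' tr <- data.frame(individual = "i1", population = "p1", chrom = "chr1",
#'                  start = c(0, 250), end = c(250, 1000),
#'                  rho = c(0.04, 0))
#' windowRho(tr, lay, 1000)$rho  # 0.01
#' @export
windowRho <- function(tracks, layout, width) {
  len <- chromLengths(layout)
  win <- grangesToBed(makeWindows(layout, width))
  nWin <- floor(len / width)
  offset <- stats::setNames(cumsum(c(0, nWin[-length(nWin)])), names(len))
  res <- lapply(split(tracks, tracks$individual), function(tr) {
    pop <- tr$population[1]
    num <- numeric(nrow(win))  # sum rho * bp
    cov <- numeric(nrow(win))
    for (ch in unique(tr$chrom)) {
      if (!ch %in% names(len)) next
      seg <- tr[tr$chrom == ch, ]
      k0 <- floor(seg$start / width)
      k1 <- floor((seg$end - 1) / width)
      reps <- k1 - k0 + 1L
      segIdx <- rep(seq_len(nrow(seg)), reps)
      k <- unlist(lapply(seq_len(nrow(seg)),
                         function(r) seq(k0[r], k1[r])))
      ws <- k * width; we <- ws + width
      ov <- pmin(seg$end[segIdx], we) - pmax(seg$start[segIdx], ws)
      ok <- k < nWin[[ch]] & ov > 0      # complete windows only
      if (!any(ok)) next
      row <- offset[[ch]] + k[ok] + 1L
      num1 <- tapply(seg$rho[segIdx][ok] * ov[ok], row, sum)
      cov1 <- tapply(ov[ok], row, sum)
      r <- as.integer(names(num1))
      num[r] <- num[r] + as.numeric(num1)
      cov[r] <- cov[r] + as.numeric(cov1)
    }
    data.frame(individual = tr$individual[1], population = pop,
               chrom = win$chrom, start = win$start, end = win$end,
               rho = ifelse(cov > 0, num / cov, NA_real_))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize windowed rho (Table-style)
#'
#' Mean, median and standard error over all (window x individual) values in
#' scope. SE = sample SD / sqrt(N); the reported interval is mean -/+ SE. N
#' is the number of non-missing values. A single-value scope gets
#' seLow = seHigh = mean with a warning.
#'
#' @param windows windowed rho data.frame from [windowRho()].
#' @param groupBy one of "chrom", "population", "total", or a character
#'   vector of grouping columns.
#' @return data.frame with columns scope, n, mean, median, seLow, seHigh.
#' @export
summarizeRho <- function(windows, groupBy = c("chrom", "population",
                                              "total")) {
  if (length(groupBy) == 1L) groupBy <- match.arg(groupBy)
  w <- windows[!is.na(windows$rho), , drop = FALSE]
  if (!nrow(w)) stop("no non-missing windows to summarize")
  key <- if (identical(groupBy, "total")) rep("total", nrow(w))
  else do.call(paste, c(w[, groupBy, drop = FALSE], sep = "/"))
  res <- lapply(split(w$rho, key), function(v) {
    m <- mean(v)
    if (length(v) < 2L) {
      warning("single-value scope: SE undefined, reporting mean only")
      se <- 0
    } else se <- stats::sd(v) / sqrt(length(v))
    data.frame(n = length(v), mean = m, median = stats::median(v),
               seLow = m - se, seHigh = m + se)
  })
  out <- cbind(scope = names(res), do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Classify recombination hotspots
#'
#' Per individual and chromosome, windows whose rho exceeds that
#' individual's chromosome mean + 2 sample SD are flagged; the reported
#' hotspot set is the union over individuals ("identified in any
#' individual"). A constant track has SD 0 and yields no hotspots.
#'
#' @param windows windowed rho data.frame from [windowRho()].
#' @return list with \code{perIndividual} (data.frame of flagged windows
#'   with individual, chrom, start, end, rho, threshold) and \code{union}
#'   (a [GRanges] of the union of flagged windows, reduced).
#' @export
classifyHotspots <- function(windows) {
  w <- windows[!is.na(windows$rho), , drop = FALSE]
  flag <- lapply(split(w, list(w$individual, w$chrom), drop = TRUE),
                 function(d) {
    if (nrow(d) < 2L) return(NULL)
    thr <- mean(d$rho) + 2 * stats::sd(d$rho)
    hit <- d$rho > thr
    if (!any(hit)) return(NULL)
    cbind(d[hit, c("individual", "chrom", "start", "end", "rho")],
          threshold = thr)
  })
  flag <- do.call(rbind, flag[!vapply(flag, is.null, TRUE)])
  if (is.null(flag))
    return(list(perIndividual = data.frame(), union = GenomicRanges::GRanges()))
  rownames(flag) <- NULL
  uni <- GenomicRanges::reduce(bedToGRanges(
    data.frame(chrom = flag$chrom, start = flag$start, end = flag$end)))
  list(perIndividual = flag, union = uni)
}
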