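# BED3+ I/O. All region tracks travel as BED (tab-separated, 0-based
# half-open) on disk and as GRanges (1-based closed) in memory; the
# conversion happens only here. The reader validates every record and names
# the offending line, which is why it is not delegated to a generic importer.

#' Convert a BED-style data.frame (0-based half-open) to GRanges
#'
#' @param df data.frame with columns chrom, start, end (0-based half-open);
#'   further columns become metadata columns.
#' @return [GRanges] (1-based closed, as usual).
#' @export
bedToGRanges <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra))
    S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

#' @rdname bedToGRanges
#' @param gr a GRanges.
#' @export
grangesToBed <- function(gr) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) df <- cbind(df, as.data.frame(mc))
  df
}

#' Read a BED3+ file into a GRanges
#'
#' Track and comment lines (\code{track}, \code{browser}, \code{#}) are
#' skipped. Coordinates are parsed as 0-based half-open and converted;
#' columns beyond the third are preserved as opaque metadata columns
#' (\code{V4}, \code{V5}, ...). Malformed records (non-integer coordinates,
#' start >= end) raise an error naming the line number.
#'
#' @param path file path.
#' @return [GRanges]; empty for an empty file.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t120", f)
#' readBed(f)
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  lines <- lines[!skip]
  lineno <- lineno[!skip]
  if (!length(lines))
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- !is.finite(start) | !is.finite(end) |
    start != floor(start) | end != floor(end)
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1L]],
         ": non-integer coordinates")
  bad <- start < 0 | start >= end
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1L]],
         ": requires 0 <= start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  maxf <- max(nf)
  if (maxf > 3L) {
    for (k in seq(4L, maxf)) {
      df[[paste0("V", k)]] <-
        vapply(fields, function(f) if (length(f) >= k) f[[k]] else NA_character_, "")
    }
  }
  bedToGRanges(df)
}

#' Write a GRanges as BED3+ (0-based half-open)
#'
#' Round-trips with [readBed()]: \code{readBed(writeBed(x))} reproduces
#' \code{x} (metadata columns written as extra text columns).
#'
#' @param gr a GRanges.
#' @param path destination path.
#' @return invisibly, the path.
#' @export
writeBed <- function(gr, path) {
  df <- grangesToBed(gr)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
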