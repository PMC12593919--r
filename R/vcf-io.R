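# VCF I/O for phased biallelic SNPs. Reading goes through vcfR; writing
# serializes the generator's own GenotypeMatrix as minimal VCFv4.2
# (GT-only), which round-trips through vcfR.

#' Write a GenotypeMatrix as a phased VCF
#'
#' Minimal VCFv4.2 with a GT-only FORMAT; phased genotypes are written
#' \code{a|b}, unphased \code{a/b}, missing \code{.|.}.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path destination path.
#' @param chromLengths optional named lengths for \code{##contig} headers.
#' @return invisibly, the path.
#' @export
writePhasedVcf <- function(g, path, chromLengths = NULL) {
  n <- nrow(g@samples)
  m <- nrow(g@sites)
  if (!is.null(g@haps)) {
    a1 <- g@haps[, seq(1L, 2L * n, by = 2L), drop = FALSE]
    a2 <- g@haps[, seq(2L, 2L * n, by = 2L), drop = FALSE]
    gt <- matrix(paste(a1, "|", a2, sep = ""), nrow = m)
  } else {
    gt <- matrix(".|.", nrow = m, ncol = n)
    gt[g@geno == 0L] <- "0/0"
    gt[g@geno == 1L] <- "0/1"
    gt[g@geno == 2L] <- "1/1"
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=claRecomb-synthetic",
           if (!is.null(chromLengths))
             sprintf("##contig=<ID=%s,length=%d>", names(chromLengths),
                     as.integer(chromLengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g@samples$id), collapse = "\t"))
  body <- if (m) paste(g@sites$chrom, g@sites$pos, g@sites$id, g@sites$ref,
                       g@sites$alt, ".", "PASS", ".", "GT",
                       apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a (phased or unphased) biallelic SNP VCF
#'
#' Parses GT fields via vcfR. Multiallelic and non-SNP records are dropped.
#' Population labels are taken from \code{populations} (named by sample id)
#' or, failing that, from the sample-name prefix before the first
#' underscore.
#'
#' @param path VCF path (plain or gzipped).
#' @param populations optional named character vector, sample id ->
#'   population.
#' @return A [GenotypeMatrix-class]; phased if every genotype uses the
#'   \code{|} separator.
#' @export
readPhasedVcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  fix <- fix[keep, , drop = FALSE]
  gtRaw <- gtRaw[keep, , drop = FALSE]
  sampleIds <- colnames(gtRaw)
  if (is.null(populations))
    populations <- stats::setNames(sub("_.*$", "", sampleIds), sampleIds)
  m <- nrow(fix); n <- length(sampleIds)
  phased <- all(grepl("|", gtRaw[!is.na(gtRaw)], fixed = TRUE))
  a1 <- suppressWarnings(
    as.integer(substr(gtRaw, 1L, 1L)))
  a2 <- suppressWarnings(
    as.integer(substr(gtRaw, 3L, 3L)))
  geno <- matrix(a1 + a2, nrow = m, ncol = n,
                 dimnames = list(NULL, sampleIds))
  haps <- NULL
  if (phased && m > 0L) {
    haps <- matrix(0L, nrow = m, ncol = 2L * n)
    haps[, seq(1L, 2L * n, by = 2L)] <- matrix(a1, nrow = m)
    haps[, seq(2L, 2L * n, by = 2L)] <- matrix(a2, nrow = m)
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                  paste0(fix$CHROM, ":", fix$POS), fix$ID),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  new("GenotypeMatrix", sites = sites,
      samples = data.frame(id = sampleIds,
                           population = unname(populations[sampleIds]),
                           stringsAsFactors = FALSE),
      geno = geno, haps = haps)
}
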