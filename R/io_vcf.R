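#' Read biallelic genotype dosages from a VCF
#'
#' Reads GT fields (via \pkg{VariantAnnotation}) and converts them to
#' alternate-allele dosages: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, missing
#' (./.) -> NA. Phased separators are accepted. Multi-allelic sites are
#' skipped with one warning giving the count.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @return samples x sites integer matrix of dosages with an attribute
#'   `sites` (data.frame `chrom`, `pos`, `id`, `ref`, `alt`) and
#'   `n_multiallelic` (number of skipped sites).
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1L
  n_multi <- sum(multi)
  if (n_multi > 0L) {
    warning(sprintf("skipped %d multi-allelic site(s)", n_multi))
    vcf <- vcf[!multi]
    alt <- alt[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  dos[norm %in% c("0/0")] <- 0L
  dos[norm %in% c("0/1", "1/0")] <- 1L
  dos[norm %in% c("1/1")] <- 2L
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = names(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_along(alt), function(i) as.character(alt[[i]])[1],
                 character(1)),
    stringsAsFactors = FALSE)
  out <- t(dos)
  rownames(out) <- colnames(gt)
  colnames(out) <- sites$id
  attr(out, "sites") <- sites
  attr(out, "n_multiallelic") <- n_multi
  out
}

#' Write a biallelic dosage matrix as a minimal VCF v4.2
#'
#' Inverse of [read_genotypes_vcf()] for round-trip testing and for the
#' synthetic generator. Dosage 0/1/2 becomes 0/0, 0/1, 1/1; NA becomes ./.
#'
#' @param dosage samples x sites matrix (0/1/2/NA).
#' @param sites data.frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(dosage, sites, path) {
  stopifnot(ncol(dosage) == nrow(sites))
  gt_code <- c("0/0", "0/1", "1/1")
  samples <- rownames(dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(j) {
    g <- dosage[, j]
    gs <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(sites$chrom[j], sites$pos[j], sites$id[j], sites$ref[j],
            sites$alt[j], ".", "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
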