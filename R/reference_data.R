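#' Bundled reference tables
#'
#' Three small published reference tables ship with the package as
#' plain-text fixtures:
#'
#' * `cobb_genotype_lsm()`: genotype least-squares means (with SD, class
#'   sizes and significance letters) for 12 RFI-associated SNPs in a
#'   commercial broiler validation population, together with the
#'   reported additive and dominance effects. Feeding the three LSMs of
#'   each SNP to [additive_dominance()] reproduces the reported effects.
#' * `group_performance()`: trait means and SDs (RFI, DFI, body weights,
#'   ADG, FCR) of the low- and high-RFI extreme groups (n = 48 per
#'   group) in a local breed and a commercial broiler line.
#' * `validation_snps()`: the 46 SNPs significantly associated
#'   (p < 0.05) with RFI breeding values in the independent validation
#'   population, with nearest genes and locations.
#'
#' @return a data.frame.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
cobb_genotype_lsm <- function() {
  read.delim(system.file("extdata", "cobb_genotype_lsm.tsv",
                         package = "poolrfi"),
             stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
group_performance <- function() {
  read.delim(system.file("extdata", "group_performance.tsv",
                         package = "poolrfi"),
             stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
validation_snps <- function() {
  read.delim(system.file("extdata", "validation_snps.tsv",
                         package = "poolrfi"),
             stringsAsFactors = FALSE)
}

#' Additive/dominance decomposition of a genotype-LSM reference table
#'
#' Applies [additive_dominance()] to each SNP of a table shaped like
#' [cobb_genotype_lsm()] (three genotype rows per SNP). The first
#' homozygote is the alphabetically first class, fixing the sign
#' convention.
#'
#' @param tab data.frame with columns `snp`, `genotype`, `lsm`.
#' @return data.frame: `snp`, `hom1`, `het`, `hom2`, their LSMs, `a_eff`,
#'   `d_eff`.
#' @export
decompose_lsm_table <- function(tab = cobb_genotype_lsm()) {
  out <- lapply(split(tab, factor(tab$snp, levels = unique(tab$snp))),
                function(d) {
    hom <- sort(d$genotype[substr(d$genotype, 1, 1) ==
                             substr(d$genotype, 2, 2)])
    het <- setdiff(d$genotype, hom)
    if (length(hom) != 2L || length(het) != 1L)
      .fail("decompose_lsm_table: SNP %s lacks three genotype classes",
            d$snp[1])
    l1 <- d$lsm[d$genotype == hom[1]]
    lh <- d$lsm[d$genotype == het]
    l2 <- d$lsm[d$genotype == hom[2]]
    ad <- additive_dominance(l1, lh, l2)
    data.frame(snp = d$snp[1], hom1 = hom[1], het = het, hom2 = hom[2],
               lsm_hom1 = l1, lsm_het = lh, lsm_hom2 = l2,
               a_eff = ad$a_eff, d_eff = ad$d_eff,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
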