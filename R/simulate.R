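#' Simulation configuration for the synthetic study
#'
#' Bundles and validates every parameter of the synthetic-data module.
#' Defaults reproduce the stated study design: a discovery flock of 400
#' birds phenotyped over a 28-day test, 48 extremes per tail pooled into
#' 2 groups x 3 replicate pools x 16 birds sequenced at ~20x mean
#' coverage, and an independent validation cohort of 779 pedigreed birds
#' (345 males, 434 females) genotyped at 191 SNPs. Where the design gives
#' no number (regression coefficients, variance components, body-weight
#' distributions) the defaults are chosen once to give realistic broiler
#' magnitudes: feed intake about 2.8 kg over the test, RFI phenotypic SD
#' about 150 g with heritability 0.3.
#'
#' @param seed integer seed; mandatory, drives every generator.
#' @param n_birds discovery flock size.
#' @param n_sires,n_dams discovery founder counts.
#' @param true_b named numeric: intercept `b0` (g), `b1` (g per g^0.75 of
#'   metabolic body weight), `b2` (g per g of weight gain) of the intake
#'   regression FI = b0 + b1 BW^0.75 + b2 WG + a + e.
#' @param sigma2_a,sigma2_e additive-genetic and residual variances of RFI
#'   (g^2).
#' @param test_days feeding-test length (d).
#' @param bw_meanlog,bw_sdlog,wg_meanlog,wg_sdlog log-normal parameters of
#'   initial body weight and weight gain (g).
#' @param n_extreme birds per phenotypic tail.
#' @param n_pools replicate pools per group; `pool_size` birds per pool.
#' @param mean_coverage mean sequencing depth per pool.
#' @param n_snps simulated loci; `n_divergent` of them planted with
#'   between-group allele-frequency difference `delta_p_planted`.
#' @param n_chroms,chrom_length toy genome shape (bp).
#' @param n_validation,n_val_males,n_val_sires,n_val_dams validation
#'   cohort sizes.
#' @param sex_effect fixed sex effect on validation RFI (g, males).
#' @param val_n_snps genotyped SNPs in the validation cohort.
#' @param snp_effects data.frame with `snp` (index), `a`, `d` (g): planted
#'   additive and dominance effects.
#' @param qpcr_n qPCR replicates per group; `ct_sd` Ct standard deviation;
#'   `ct_ref_mean` reference-gene Ct; `ct_target_mean` target Ct in the
#'   HRFI (reference) group; `qpcr_fold` named numeric of true LRFI/HRFI
#'   fold changes per assayed gene.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_birds = 400L, n_sires = 75L, n_dams = 153L,
                       true_b = c(b0 = 500, b1 = 10, b2 = 1.4),
                       sigma2_a = 6750, sigma2_e = 15750,
                       test_days = 28L,
                       bw_meanlog = log(820), bw_sdlog = 0.12,
                       wg_meanlog = log(540), wg_sdlog = 0.25,
                       n_extreme = 48L, n_pools = 3L, pool_size = 16L,
                       mean_coverage = 20,
                       n_snps = 10000L, n_divergent = 5L,
                       delta_p_planted = 0.8,
                       n_chroms = 5L, chrom_length = 500000L,
                       n_validation = 779L, n_val_males = 345L,
                       n_val_sires = 40L, n_val_dams = 120L,
                       sex_effect = 20,
                       val_n_snps = 191L,
                       snp_effects = data.frame(snp = 1:5,
                                                a = c(12, 10, 8, -10, 9),
                                                d = c(0, 5, -4, 0, 8)),
                       qpcr_n = 8L, ct_sd = 0.25, ct_ref_mean = 15,
                       ct_target_mean = 20,
                       qpcr_fold = c(NOS1 = 2, PHKG1 = 0.5, NEU3 = 1,
                                     PIP5K1B = 1.5)) {
  if (missing(seed)) .fail("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  if (sigma2_a < 0 || sigma2_e < 0) .fail("sim_config: variances must be >= 0")
  if (delta_p_planted < 0 || delta_p_planted > 1)
    .fail("sim_config: delta_p_planted must be in [0, 1]")
  if (n_divergent > n_snps) .fail("sim_config: n_divergent > n_snps")
  if (n_pools * pool_size > n_extreme)
    .fail("sim_config: n_pools * pool_size exceeds group size")
  if (pool_size < 1L || n_pools < 1L) .fail("sim_config: empty pool layout")
  if (n_val_males > n_validation)
    .fail("sim_config: n_val_males > n_validation")
  if (!all(c("snp", "a", "d") %in% names(snp_effects)))
    .fail("sim_config: snp_effects needs columns snp, a, d")
  structure(cfg, class = "sim_config")
}

# recursive additive-genetic values down a sorted pedigree:
# founders ~ N(0, s2a); offspring = midparent + N(0, s2a/2) (inbreeding
# ignored; founders-only matings keep this exact)
sim_breeding_values <- function(ped, sigma2_a) {
  bv <- setNames(numeric(nrow(ped)), ped$animal)
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire[i]; d <- ped$dam[i]
    par_mean <- 0; mend_var <- sigma2_a
    if (!is.na(s) || !is.na(d)) {
      par_mean <- mean(c(if (!is.na(s)) bv[[s]], if (!is.na(d)) bv[[d]]))
      mend_var <- sigma2_a / 2
    }
    bv[i] <- par_mean + rnorm(1, 0, sqrt(mend_var))
  }
  bv
}

#' Simulate the discovery flock: phenotypes plus pedigree plus truth
#'
#' Generates the inverse of the RFI regression: body weight and weight
#' gain are drawn log-normally, then FI = b0 + b1 BW^0.75 + b2 WG + a + e
#' with `a` from a pedigree-structured additive model. Sexes are balanced.
#'
#' @param config a [sim_config()].
#' @return list with `phenotypes` (one row per bird), `pedigree`
#'   (founders then offspring) and `truth` (true breeding values and
#'   generative parameters).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  sires <- sprintf("S%03d", seq_len(config$n_sires))
  dams <- sprintf("D%03d", seq_len(config$n_dams))
  n <- config$n_birds
  birds <- sprintf("B%04d", seq_len(n))
  ped <- data.frame(
    animal = c(sires, dams, birds),
    sire = c(rep(NA_character_, length(sires) + length(dams)),
             sample(sires, n, replace = TRUE)),
    dam = c(rep(NA_character_, length(sires) + length(dams)),
            sample(dams, n, replace = TRUE)),
    sex = c(rep("M", length(sires)), rep("F", length(dams)),
            sample(rep(c("M", "F"), length.out = n))),
    stringsAsFactors = FALSE)
  bv <- sim_breeding_values(ped, config$sigma2_a)
  idx <- match(birds, ped$animal)
  bw <- rlnorm(n, config$bw_meanlog, config$bw_sdlog)
  wg <- rlnorm(n, config$wg_meanlog, config$wg_sdlog)
  e <- rnorm(n, 0, sqrt(config$sigma2_e))
  b <- config$true_b
  fi <- b[["b0"]] + b[["b1"]] * bw^0.75 + b[["b2"]] * wg + bv[idx] + e
  phen <- data.frame(
    bird_id = birds,
    sex = ped$sex[idx],
    sire_id = ped$sire[idx],
    dam_id = ped$dam[idx],
    initial_bw = bw,
    final_bw = bw + wg,
    total_fi = fi,
    test_days = config$test_days,
    stringsAsFactors = FALSE)
  list(phenotypes = phen, pedigree = ped,
       truth = list(breeding_values = bv, true_b = b,
                    sigma2_a = config$sigma2_a, sigma2_e = config$sigma2_e))
}

#' Simulate pooled allele counts (sync) with planted divergent loci
#'
#' For every locus a low-group and a high-group base frequency are drawn;
#' at `n_divergent` planted loci they differ by exactly
#' `delta_p_planted`, elsewhere they are equal. Each replicate pool then
#' draws its 2 x `pool_size` chromosomes binomially from the group
#' frequency, and read counts are drawn binomially from the pool
#' frequency at Poisson (>= 1) coverage. The two-stage draw reproduces
#' the extra-binomial variance that pooled F_ST corrections assume.
#'
#' @param config a [sim_config()].
#' @param coverage optional fixed coverage overriding the Poisson draw
#'   (used for infinite-coverage checks).
#' @return list with `sync` (a `pool_sync`) and `truth` (`divergent`
#'   locus indices, per-locus group frequencies `p_low`, `p_high`).
#' @export
simulate_pool_counts <- function(config, coverage = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  m <- config$n_snps
  chrom <- sort(sample(sprintf("chr%d", seq_len(config$n_chroms)), m,
                       replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ii)
    sort(sample.int(config$chrom_length, length(ii)))), use.names = FALSE)
  nuc <- c("A", "T", "C", "G")
  ref <- sample(nuc, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), character(1))
  p_common <- runif(m, 0.05, 0.95)
  p_low <- p_common
  p_high <- p_common
  divergent <- sort(sample.int(m, config$n_divergent))
  if (length(divergent)) {
    half <- config$delta_p_planted / 2
    mid <- runif(length(divergent), half + 0.02, 1 - half - 0.02)
    sgn <- sample(c(-1, 1), length(divergent), replace = TRUE)
    p_low[divergent] <- mid - sgn * half
    p_high[divergent] <- mid + sgn * half
  }
  n_pool <- 2L * config$n_pools
  layout <- data.frame(
    group = rep(c("LRFI", "HRFI"), each = config$n_pools),
    replicate = rep(seq_len(config$n_pools), 2L),
    n_ind = config$pool_size)
  counts <- array(0L, dim = c(m, n_pool, 6L),
                  dimnames = list(NULL, NULL, SYNC_BASES))
  two_n <- 2L * config$pool_size
  for (j in seq_len(n_pool)) {
    p <- if (layout$group[j] == "LRFI") p_low else p_high
    q <- rbinom(m, two_n, p) / two_n
    cov <- if (is.null(coverage)) {
      cv <- rpois(m, config$mean_coverage)
      while (any(cv == 0L)) cv[cv == 0L] <- rpois(sum(cv == 0L),
                                                  config$mean_coverage)
      cv
    } else rep(as.integer(coverage), m)
    alt_reads <- rbinom(m, cov, q)
    slab <- matrix(0L, m, 6L)
    slab[cbind(seq_len(m), match(alt, SYNC_BASES))] <- alt_reads
    slab[cbind(seq_len(m), match(ref, SYNC_BASES))] <-
      slab[cbind(seq_len(m), match(ref, SYNC_BASES))] + (cov - alt_reads)
    counts[, j, ] <- slab
  }
  sync <- new_pool_sync(
    sites = data.frame(chrom = chrom, pos = pos, ref = ref,
                       stringsAsFactors = FALSE),
    counts = counts, layout = layout)
  list(sync = sync,
       truth = list(divergent = divergent, p_low = p_low, p_high = p_high,
                    alt = alt))
}

#' Simulate the validation cohort: genotypes, RFI, pedigree, truth
#'
#' Offspring of unrelated founders, Hardy-Weinberg genotypes at uniform
#' allele frequencies, phenotype
#' `RFI = sex effect + sum over effect SNPs of a (g - 1) + d [g == 1] +
#' polygenic + residual`.
#'
#' @param config a [sim_config()]; `snp_effects` must list at least one
#'   SNP.
#' @return list with `dosage` (samples x SNPs), `sites`, `genotype_labels`
#'   (character matrix, e.g. "AG"), `phenotypes`, `pedigree`, `truth`.
#' @export
simulate_validation_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$snp_effects) < 1L)
    .fail("simulate_validation_cohort: snp_effects must list >= 1 SNP")
  set.seed(derive_seed(config$seed, 3L))
  n <- config$n_validation
  m <- config$val_n_snps
  sires <- sprintf("VS%03d", seq_len(config$n_val_sires))
  dams <- sprintf("VD%03d", seq_len(config$n_val_dams))
  birds <- sprintf("V%04d", seq_len(n))
  sex <- sample(rep(c("M", "F"), c(config$n_val_males,
                                   n - config$n_val_males)))
  ped <- data.frame(
    animal = c(sires, dams, birds),
    sire = c(rep(NA_character_, length(sires) + length(dams)),
             sample(sires, n, replace = TRUE)),
    dam = c(rep(NA_character_, length(sires) + length(dams)),
            sample(dams, n, replace = TRUE)),
    sex = c(rep("M", length(sires)), rep("F", length(dams)), sex),
    stringsAsFactors = FALSE)
  freq <- runif(m, 0.1, 0.9)
  eff <- config$snp_effects
  if (any(eff$snp < 1L | eff$snp > m))
    .fail("simulate_validation_cohort: snp_effects index out of range")
  if (any(freq[eff$snp] <= 0 | freq[eff$snp] >= 1))
    .fail("simulate_validation_cohort: effect SNP frequency 0 or 1")
  dosage <- vapply(freq, function(p) rbinom(n, 2L, p), integer(n))
  nuc <- c("A", "T", "C", "G")
  ref <- sample(nuc, m, replace = TRUE)
  altb <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), character(1))
  snp_id <- sprintf("snp%04d", seq_len(m))
  chrom <- sample(sprintf("chr%d", seq_len(config$n_chroms)), m, replace = TRUE)
  sites <- data.frame(chrom = chrom,
                      pos = sample.int(config$chrom_length, m),
                      id = snp_id, ref = ref, alt = altb,
                      stringsAsFactors = FALSE)
  rownames(dosage) <- birds
  colnames(dosage) <- snp_id
  # genotype class labels with alleles in alphabetical order within class
  geno_lab <- dosage
  labels <- vapply(seq_len(m), function(j) {
    al <- c(ref[j], altb[j])
    c(paste0(al[1], al[1]),
      paste(sort(al), collapse = ""),
      paste0(al[2], al[2]))
  }, character(3))
  geno_lab <- matrix(labels[cbind(as.vector(dosage) + 1L,
                                  rep(seq_len(m), each = n))],
                     nrow = n, dimnames = dimnames(dosage))
  bv <- sim_breeding_values(ped, config$sigma2_a)
  idx <- match(birds, ped$animal)
  snp_part <- numeric(n)
  for (k in seq_len(nrow(eff))) {
    g <- dosage[, eff$snp[k]]
    snp_part <- snp_part + eff$a[k] * (g - 1) + eff$d[k] * (g == 1L)
  }
  y <- config$sex_effect * (sex == "M") + snp_part + bv[idx] +
    rnorm(n, 0, sqrt(config$sigma2_e))
  phen <- data.frame(bird_id = birds, sex = sex, rfi = y,
                     stringsAsFactors = FALSE)
  list(dosage = dosage, sites = sites, genotype_labels = geno_lab,
       phenotypes = phen, pedigree = ped,
       truth = list(breeding_values = bv, snp_effects = eff, freq = freq,
                    sex_effect = config$sex_effect))
}

#' Simulate a toy gene set and reference genome
#'
#' Non-overlapping genes are tiled along each chromosome with random
#' 2-exon structure; the first exon carries a CDS whose length is a
#' multiple of 3. Random uniform reference sequences are generated so
#' codon-level categorization is exercised end to end.
#'
#' @param config a [sim_config()].
#' @param genes_per_chrom genes tiled per chromosome (default 20).
#' @return list with `genes` (gene-model list, see [read_gff3_genes()])
#'   and `ref_seqs` (named character vector of chromosome sequences).
#' @export
simulate_gene_models <- function(config, genes_per_chrom = 20L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 5L))
  nuc <- c("A", "C", "G", "T")
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  ref_seqs <- setNames(vapply(chroms, function(ch)
    paste(sample(nuc, config$chrom_length, replace = TRUE), collapse = ""),
    character(1)), chroms)
  slot <- config$chrom_length %/% genes_per_chrom
  genes <- list()
  for (ch in chroms) {
    for (k in seq_len(genes_per_chrom)) {
      lo <- (k - 1L) * slot + 1L
      start <- lo + sample.int(slot %/% 4L, 1L)
      len <- sample(2000:8000, 1L)
      end <- min(start + len - 1L, lo + slot - 100L)
      exon1_end <- start + 3L * sample(100:300, 1L) - 1L
      exon2_start <- min(exon1_end + sample(200:800, 1L), end - 10L)
      genes[[length(genes) + 1L]] <- list(
        gene_id = sprintf("G%s_%02d", sub("chr", "", ch), k),
        chrom = ch, start = start, end = end,
        strand = sample(c("+", "-"), 1L),
        cds = data.frame(start = start, end = exon1_end, phase = 0L),
        exons = data.frame(start = c(start, exon2_start),
                           end = c(exon1_end, end)))
    }
  }
  list(genes = genes, ref_seqs = ref_seqs)
}

#' Simulate a two-group qPCR Ct table
#'
#' Reference-gene Ct means are equal across groups by construction;
#' target-gene Ct in the LRFI group is shifted by -log2(fold) relative to
#' HRFI so that the true LRFI/HRFI fold change is `qpcr_fold`.
#'
#' @param config a [sim_config()].
#' @return list with `ct` (Ct table) and `truth` (true fold per gene).
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 4L))
  genes <- names(config$qpcr_fold)
  n <- config$qpcr_n
  rows <- lapply(genes, function(g) {
    shift <- -log2(config$qpcr_fold[[g]])
    data.frame(
      sample_id = paste0(g, "_", rep(c("H", "L"), each = n),
                         seq_len(2 * n)),
      group = rep(c("HRFI", "LRFI"), each = n),
      gene = g,
      ct_target = c(rnorm(n, config$ct_target_mean, config$ct_sd),
                    rnorm(n, config$ct_target_mean + shift, config$ct_sd)),
      ct_reference = rnorm(2 * n, config$ct_ref_mean, config$ct_sd),
      stringsAsFactors = FALSE)
  })
  list(ct = do.call(rbind, rows),
       truth = list(fold = config$qpcr_fold))
}
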