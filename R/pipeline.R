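#' Read and validate a pipeline configuration
#'
#' The configuration is JSON with these blocks:
#' * `simulate`: arguments for [sim_config()] (`seed` mandatory) — when
#'   present, every input is generated in memory;
#' * `inputs`: alternatively, paths: `phenotypes`, `sync`, `layout`
#'   (pool-layout CSV: `group`, `replicate`, `n_ind`), `gff`, `vcf`,
#'   `validation_phenotypes`, `pedigree`, `ct`;
#' * `screen`: arguments for [screen_config()];
#' * `window`: gene-assignment flank (bp, default 50000);
#' * `n_extreme`, `n_pools`, `pool_size`, `sex_balanced`: pooling design;
#' * `h2`: fixed heritability for the validation model (omit to run
#'   REML);
#' * `qpcr_reference_group` (default "HRFI").
#'
#' @param config path to a JSON file, or an equivalent list.
#' @return list of class `pipeline_config` with a `config_hash`
#'   attribute (md5 of the canonical JSON).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .fail("pipeline_config: no such file: %s", config)
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else cfg <- config
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    .fail("pipeline_config: need a 'simulate' or an 'inputs' block")
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      .fail("pipeline_config: missing input file(s): %s",
            paste(missing, collapse = ", "))
  }
  cfg$window <- if (is.null(cfg$window)) 50000L else as.integer(cfg$window)
  cfg$n_extreme <- if (is.null(cfg$n_extreme)) 48L else as.integer(cfg$n_extreme)
  cfg$n_pools <- if (is.null(cfg$n_pools)) 3L else as.integer(cfg$n_pools)
  cfg$pool_size <- if (is.null(cfg$pool_size)) 16L
    else as.integer(cfg$pool_size)
  cfg$sex_balanced <- isTRUE(cfg$sex_balanced)
  cfg$qpcr_reference_group <- if (is.null(cfg$qpcr_reference_group)) "HRFI"
    else cfg$qpcr_reference_group
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  structure(cfg, class = "pipeline_config", config_hash = hash)
}

# JSON-decoded simulate blocks arrive as plain lists; coerce the frame-
# valued field before dispatching to sim_config()
sim_config_from_list <- function(args) {
  if (is.null(args$seed)) .fail("simulate block: seed is mandatory")
  if (!is.null(args$snp_effects))
    args$snp_effects <- as.data.frame(args$snp_effects)
  do.call(sim_config, args)
}

#' Run the full analysis end to end
#'
#' Stages: phenotype regression and pooling design; pooled SNP screen;
#' candidate gene assignment and categorization; validation-population
#' association; qPCR expression comparison. With a `simulate` block,
#' every input comes from the synthetic module and the run report is
#' cross-checked against the generator's ground truth. Stage outputs are
#' written to `out_dir` (TSV, with the config hash and stage name in a
#' comment header); writes are atomic (temp file then rename).
#'
#' @param config a [pipeline_config()], a list, or a JSON path.
#' @param out_dir output directory (created if needed); NULL for
#'   in-memory results only.
#' @return list of class `pipeline_result` with per-stage outputs and
#'   `report` (counts in/out per stage, thresholds, ground-truth
#'   bookkeeping when simulated).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  hash <- attr(config, "config_hash")
  report <- list(config_hash = hash)
  simulated <- !is.null(config$simulate)
  truth <- NULL

  if (simulated) {
    scfg <- sim_config_from_list(config$simulate)
    phen_sim <- simulate_phenotypes(scfg)
    pool_sim <- simulate_pool_counts(scfg)
    gene_sim <- simulate_gene_models(scfg)
    val_sim <- simulate_validation_cohort(scfg)
    qpcr_sim <- simulate_qpcr(scfg)
    phenotypes <- phen_sim$phenotypes
    sync <- pool_sim$sync
    genes <- gene_sim$genes
    ref_seqs <- gene_sim$ref_seqs
    ct <- qpcr_sim$ct
    truth <- list(phenotypes = phen_sim$truth, pools = pool_sim$truth,
                  validation = val_sim$truth, qpcr = qpcr_sim$truth)
  } else {
    inp <- config$inputs
    phenotypes <- read_phenotypes(inp$phenotypes)
    layout <- read.csv(inp$layout, stringsAsFactors = FALSE)
    sync <- read_sync(inp$sync, layout)
    genes <- if (!is.null(inp$gff)) read_gff3_genes(inp$gff) else list()
    ref_seqs <- NULL
    ct <- if (!is.null(inp$ct)) read_ct_table(inp$ct) else NULL
  }

  # stage 1: RFI phenotype, extremes, pools
  rfi <- fit_rfi(phenotypes)
  extremes <- select_extremes(rfi$records, config$n_extreme)
  pools_low <- build_pools(extremes$low, config$n_pools, config$pool_size,
                           config$sex_balanced)
  pools_high <- build_pools(extremes$high, config$n_pools, config$pool_size,
                            config$sex_balanced)
  summary_tab <- group_summary(extremes$low, extremes$high)
  report$phenotype <- list(n_birds = nrow(phenotypes),
                           n_low = nrow(extremes$low),
                           n_high = nrow(extremes$high),
                           n_pools = 2L * config$n_pools)

  # stage 2: pooled screen
  scr_cfg <- do.call(screen_config, as.list(config$screen))
  screen <- screen_sites(sync, scr_cfg)
  candidates <- screen$results[screen$results$candidate, , drop = FALSE]
  report$screen <- screen$report

  # stage 3: annotation
  annot <- if (length(genes) && nrow(candidates)) {
    annotate_candidates(candidates, genes, ref_seqs, config$window)
  } else candidates
  report$annotation <- list(
    n_candidates = nrow(candidates),
    categories = if (nrow(candidates) && length(genes))
      setNames(as.list(annotation_summary(annot)$n),
               annotation_summary(annot)$category) else NULL)

  # stage 4: validation association
  assoc <- NULL
  if (simulated) {
    assoc <- validate_assoc(val_sim$dosage, val_sim$genotype_labels,
                            val_sim$phenotypes, val_sim$pedigree,
                            h2 = config$h2)
  } else if (!is.null(config$inputs$vcf)) {
    if (is.null(config$inputs$pedigree))
      .fail("run_pipeline: validation stage enabled but no pedigree given")
    dos <- read_genotypes_vcf(config$inputs$vcf)
    sites <- attr(dos, "sites")
    labels3 <- vapply(seq_len(nrow(sites)), function(j) {
      al <- c(sites$ref[j], sites$alt[j])
      c(paste0(al[1], al[1]), paste(sort(al), collapse = ""),
        paste0(al[2], al[2]))
    }, character(3))
    lab <- matrix(labels3[cbind(as.vector(dos) + 1L,
                                rep(seq_len(ncol(dos)), each = nrow(dos)))],
                  nrow = nrow(dos), dimnames = dimnames(dos))
    vphen <- read_phenotypes(config$inputs$validation_phenotypes)
    if (is.null(vphen$rfi)) vphen$rfi <- fit_rfi(vphen)$records$rfi
    ped <- read_pedigree(config$inputs$pedigree)
    assoc <- validate_assoc(dos, lab, vphen, ped, h2 = config$h2)
  }
  if (!is.null(assoc))
    report$validation <- list(
      n_birds = assoc$n_records,
      n_snps = nrow(assoc$assoc),
      n_significant = sum(assoc$assoc$significant),
      n_genotype_effects = length(assoc$genotype_effects),
      h2 = assoc$varcomp$h2)

  # stage 5: qPCR
  expr <- NULL
  if (!is.null(ct)) {
    dd <- ddct(ct, config$qpcr_reference_group)
    tt <- group_ttest(dd$samples)
    expr <- list(ddct = dd, ttest = tt)
    report$qpcr <- list(n_genes = nrow(tt),
                        n_significant = sum(tt$p_value < 0.05))
  }

  if (simulated) {
    planted <- truth$pools$divergent
    cand_idx <- match(paste(candidates$chrom, candidates$pos),
                      paste(sync$sites$chrom, sync$sites$pos))
    report$ground_truth <- list(
      n_snps_simulated = nrow(sync$sites),
      n_planted = length(planted),
      n_planted_recovered = sum(planted %in% cand_idx),
      n_validation_effect_snps = nrow(truth$validation$snp_effects))
  }

  result <- structure(
    list(rfi_fit = rfi$fit, rfi_records = rfi$records,
         extremes = extremes, pools = list(low = pools_low,
                                           high = pools_high),
         group_summary = summary_tab, screen = screen,
         candidates = candidates, annotation = annot,
         validation = assoc, expression = expr,
         report = report, truth = truth),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    atomic_write <- function(df, name, stage) {
      tmp <- tempfile(tmpdir = out_dir)
      write_results_table(df, tmp,
                          header = c(sprintf("config_hash=%s", hash),
                                     sprintf("stage=%s", stage)))
      file.rename(tmp, file.path(out_dir, name))
    }
    atomic_write(rfi$records, "rfi.tsv", "phenotype")
    atomic_write(summary_tab, "group_summary.tsv", "phenotype")
    atomic_write(screen$results, "screen.tsv", "screen")
    atomic_write(annot, "annotation.tsv", "annotation")
    if (!is.null(assoc)) atomic_write(assoc$assoc, "assoc.tsv", "validation")
    if (!is.null(expr)) atomic_write(expr$ddct$genes, "expression.tsv", "qpcr")
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  result
}

#' Pool-versus-individual allele-frequency concordance
#'
#' Desk analogue of cross-method SNP verification: compares
#' pool-estimated allele frequencies with frequencies derived from
#' individual genotypes at the shared SNPs. Similarity is the fraction of
#' shared SNPs whose absolute frequency difference is within `tol`.
#'
#' @param pool_freqs data.frame `chrom`, `pos`, `freq`.
#' @param indiv_freqs data.frame `chrom`, `pos`, `freq`.
#' @param tol agreement tolerance on the frequency scale (default 0.1).
#' @return list with `per_snp` (shared SNPs with both frequencies and
#'   `abs_diff`) and `similarity`.
#' @export
concordance <- function(pool_freqs, indiv_freqs, tol = 0.1) {
  merged <- merge(pool_freqs, indiv_freqs, by = c("chrom", "pos"),
                  suffixes = c("_pool", "_indiv"))
  if (nrow(merged) == 0L) .fail("concordance: no shared SNPs")
  merged$abs_diff <- abs(merged$freq_pool - merged$freq_indiv)
  list(per_snp = merged, similarity = mean(merged$abs_diff <= tol))
}

#' Minimal command-line entry point
#'
#' Supports `poolrfi run --config cfg.json --out dir` and
#' `poolrfi simulate --config cfg.json --out dir` (the latter writes the
#' synthetic inputs as files: phenotype/pedigree CSV, sync, GFF3, VCF,
#' Ct CSV, ground-truth JSON). Finer-grained steps are R functions.
#'
#' @param args character vector, default the trailing command line.
#' @return invisibly, the pipeline result or the output directory.
#' @export
poolrfi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: poolrfi (run|simulate) --config <json> --out <dir>"
  if (length(args) < 1L) .fail(usage)
  cmd <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) != 1L || i == length(args)) .fail(usage)
    args[i + 1L]
  }
  if (cmd == "run") {
    invisible(run_pipeline(opt("--config"), opt("--out")))
  } else if (cmd == "simulate") {
    cfg <- pipeline_config(opt("--config"))
    out <- opt("--out")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    scfg <- sim_config_from_list(cfg$simulate)
    ph <- simulate_phenotypes(scfg)
    write_phenotypes(ph$phenotypes, file.path(out, "phenotypes.csv"))
    write_pedigree(ph$pedigree, file.path(out, "pedigree.csv"))
    pc <- simulate_pool_counts(scfg)
    write_sync(pc$sync, file.path(out, "pools.sync"))
    write.csv(pc$sync$layout, file.path(out, "layout.csv"),
              row.names = FALSE, quote = FALSE)
    gm <- simulate_gene_models(scfg)
    write_gff3_genes(gm$genes, file.path(out, "genes.gff3"))
    vc <- simulate_validation_cohort(scfg)
    write_genotypes_vcf(vc$dosage, vc$sites,
                        file.path(out, "validation.vcf"))
    write_pedigree(vc$pedigree, file.path(out, "validation_pedigree.csv"))
    write.csv(vc$phenotypes, file.path(out, "validation_phenotypes.csv"),
              row.names = FALSE, quote = FALSE)
    qp <- simulate_qpcr(scfg)
    write.csv(qp$ct, file.path(out, "ct.csv"), row.names = FALSE,
              quote = FALSE)
    jsonlite::write_json(
      list(pool_truth = pc$truth, validation_truth = vc$truth,
           qpcr_truth = qp$truth),
      file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    invisible(out)
  } else .fail(usage)
}
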