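toy_gene <- function(id, chrom, start, end, strand = "+",
                     cds = NULL, exons = NULL) {
  list(gene_id = id, chrom = chrom, start = start, end = end,
       strand = strand,
       cds = if (is.null(cds)) data.frame(start = numeric(),
                                          end = numeric(),
                                          phase = integer()) else cds,
       exons = if (is.null(exons)) data.frame(start = numeric(),
                                              end = numeric()) else exons)
}

test_that("assign_genes is inclusive at exactly the window size", {
  genes <- list(toy_gene("g1", "chr1", 100000, 110000))
  hit <- assign_genes(data.frame(chrom = "chr1", pos = 60000), genes, 50000)
  expect_equal(hit$gene_id, "g1")
  expect_equal(hit$distance, 40000L)

  at_window <- assign_genes(data.frame(chrom = "chr1", pos = 50000),
                            genes, 50000)
  expect_equal(nrow(at_window), 1L)  # distance exactly 50,000: assigned
  expect_equal(at_window$distance, 50000L)
  beyond <- assign_genes(data.frame(chrom = "chr1", pos = 49999),
                         genes, 50000)
  expect_equal(nrow(beyond), 0L)    # 50,001 bp away: not assigned
  after <- assign_genes(data.frame(chrom = "chr1", pos = 160001),
                        genes, 50000)
  expect_equal(nrow(after), 0L)
  expect_equal(nrow(assign_genes(data.frame(chrom = "chr1", pos = 160000),
                                 genes, 50000)), 1L)
})

test_that("assign_genes equals the brute-force all-pairs interval check", {
  set.seed(55)
  genes <- lapply(1:40, function(i) {
    chrom <- sample(c("chr1", "chr2"), 1)
    s <- sample.int(2e5, 1)
    toy_gene(paste0("g", i), chrom, s, s + sample.int(20000, 1))
  })
  snps <- data.frame(chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
                     pos = sample.int(250000, 300))
  window <- 5000
  got <- assign_genes(snps, genes, window)
  want <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    rows <- lapply(genes, function(g) {
      if (g$chrom != snps$chrom[i]) return(NULL)
      d <- if (snps$pos[i] < g$start) g$start - snps$pos[i]
      else if (snps$pos[i] > g$end) snps$pos[i] - g$end else 0
      if (d <= window)
        data.frame(snp_index = i, gene_id = g$gene_id,
                   distance = as.integer(d), stringsAsFactors = FALSE)
      else NULL
    })
    do.call(rbind, rows)
  }))
  want <- want[order(want$snp_index, want$distance, want$gene_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("codon-level categorization follows the genetic code, strand-aware", {
  # + strand, CDS = GAA GAT TGC (E D C)
  g <- make_codon_gene("GAAGATTGC", cds_start = 101L)
  genes <- list(g$gene)
  # third position of codon 1: GAA -> GAG, Glu -> Glu
  expect_equal(categorize_snp("chr1", 103, "A", "G", genes,
                              g$ref_seqs)$category, "exon_synonymous")
  # second position: GAA -> GTA, Glu -> Val
  expect_equal(categorize_snp("chr1", 102, "A", "T", genes,
                              g$ref_seqs)$category, "exon_missense")
  # stop gain: TGC -> TGA is neither synonymous nor missense here
  expect_equal(categorize_snp("chr1", 109, "C", "A", genes,
                              g$ref_seqs)$category, "exon_other")

  # same coding change on the minus strand: genomic alleles complemented
  gm <- make_codon_gene("GAAGATTGC", cds_start = 101L, strand = "-")
  genes_m <- list(gm$gene)
  # coding GAA->GAG third base is genomic position cds_start (last on -)
  expect_equal(categorize_snp("chr1", gm$cds_end - 2, "T", "C", genes_m,
                              gm$ref_seqs)$category, "exon_synonymous")
  expect_equal(categorize_snp("chr1", gm$cds_end - 1, "T", "A", genes_m,
                              gm$ref_seqs)$category, "exon_missense")
})

test_that("precedence: CDS > exon > intron > upstream/downstream > intergenic", {
  g <- toy_gene("g1", "chr1", 1000, 9000, strand = "+",
                cds = data.frame(start = 2000, end = 2299, phase = 0L),
                exons = data.frame(start = c(2000, 5000),
                                   end = c(2299, 5499)))
  genes <- list(g)
  expect_equal(categorize_snp("chr1", 2100, "A", "G", genes)$category,
               "exon_other")  # CDS hit but no reference sequence
  expect_equal(categorize_snp("chr1", 5100, "A", "G", genes)$category,
               "exon_other")  # non-coding exon
  expect_equal(categorize_snp("chr1", 3000, "A", "G", genes)$category,
               "intron")
  expect_equal(categorize_snp("chr1", 500, "A", "G", genes)$category,
               "upstream")
  expect_equal(categorize_snp("chr1", 9500, "A", "G", genes)$category,
               "downstream")
  # strand flips the upstream/downstream call
  gm <- toy_gene("g2", "chr1", 1000, 9000, strand = "-")
  expect_equal(categorize_snp("chr1", 500, "A", "G", list(gm))$category,
               "downstream")
  expect_equal(categorize_snp("chr1", 99999, "A", "G", genes)$category,
               "intergenic")
})

test_that("annotation assigns every SNP exactly one category; totals add up", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length = 100000)
  gm <- simulate_gene_models(cfg, genes_per_chrom = 8)
  set.seed(1)
  snps <- data.frame(chrom = sample(c("chr1", "chr2", "chr9"), 60,
                                    replace = TRUE),
                     pos = sample.int(100000, 60),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_candidates(snps, gm$genes, gm$ref_seqs),
                 "chr9")
  expect_true(all(ann$category %in% c("intergenic", "upstream",
                                      "downstream", "intron",
                                      "exon_synonymous", "exon_missense",
                                      "exon_other")))
  summ <- annotation_summary(ann)
  expect_equal(sum(summ$n), nrow(snps))
  expect_true(all((ann$category == "intergenic") == (ann$gene_ids == "")))
})
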