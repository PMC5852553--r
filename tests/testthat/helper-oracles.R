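# Independent brute-force oracles used across the suite. These stay
# deliberately naive and share no code with the implementation paths
# they check.

# exact recursive kinship (coefficient of coancestry); A = 2 * kinship
oracle_kinship_matrix <- function(ped) {
  ids <- ped$animal
  n <- length(ids)
  sire <- match(ped$sire, ids)
  dam <- match(ped$dam, ids)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + f(sire[i], dam[i]))
    } else {
      # recurse on the younger animal (larger index: parents precede
      # offspring in the fixtures used here)
      a <- max(i, j); b <- min(i, j)
      0.5 * (f(sire[a], b) + f(dam[a], b))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# random pedigree with founders first (parents always precede offspring)
random_pedigree <- function(n_founders, n_offspring, seed) {
  set.seed(seed)
  ids <- sprintf("A%03d", seq_len(n_founders + n_offspring))
  sire <- rep(NA_character_, n_founders + n_offspring)
  dam <- rep(NA_character_, n_founders + n_offspring)
  for (k in seq_len(n_offspring)) {
    i <- n_founders + k
    parents <- sample(seq_len(i - 1L), 2L)
    sire[i] <- ids[parents[1]]
    dam[i] <- ids[parents[2]]
  }
  data.frame(animal = ids, sire = sire, dam = dam,
             sex = sample(c("M", "F"), length(ids), replace = TRUE),
             stringsAsFactors = FALSE)
}

# the pi-based pooled F_ST, written straight from its definition
oracle_pooled_fst <- function(ref1, alt1, ref2, alt2, chrom1, chrom2) {
  pi_hat <- function(alt, cov, chroms) {
    p <- alt / cov
    C <- min(cov, chroms)
    if (C <= 1) return(0)
    C / (C - 1) * 2 * p * (1 - p)
  }
  c1 <- ref1 + alt1; c2 <- ref2 + alt2
  pi1 <- pi_hat(alt1, c1, chrom1)
  pi2 <- pi_hat(alt2, c2, chrom2)
  piT <- pi_hat(alt1 + alt2, c1 + c2, chrom1 + chrom2)
  if (piT == 0) return(0)
  max(0, (piT - (pi1 + pi2) / 2) / piT)
}

# a small two-pool sync fixture written by hand
make_test_sync <- function() {
  f <- tempfile(fileext = ".sync")
  writeLines(c("chr1\t100\tA\t16:4:0:0:0:0\t10:10:0:0:0:0",
               "chr1\t250\tC\t0:0:12:8:0:0\t0:0:20:0:0:0",
               "chr2\t50\tG\t5:0:0:15:0:0\t9:0:0:11:0:0"), f)
  f
}

# minimal single-gene GFF3 (gene 1000-2000, CDS 1100-1399, + strand)
make_test_gff <- function() {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=gene1",
    "chr1\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\ttest\texon\t1000\t1500\t.\t+\t.\tParent=tx1",
    "chr1\ttest\texon\t1700\t2000\t.\t+\t.\tParent=tx1",
    "chr1\ttest\tCDS\t1100\t1399\t.\t+\t0\tID=cds1;Parent=tx1"), f)
  f
}

make_test_vcf <- function() {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t1/1",
    "chr1\t300\trs3\tG\tT,A\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"), f)
  f
}

# standard genetic code, frozen independently of Biostrings
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# build a one-gene model whose CDS is an explicit sequence on chr1
# starting at `cds_start` (+ strand), gene spanning the CDS with flanks
make_codon_gene <- function(cds_seq, cds_start = 101L, strand = "+",
                            chrom_len = 1000L) {
  stopifnot(nchar(cds_seq) %% 3 == 0)
  pre <- paste(rep("A", cds_start - 1L), collapse = "")
  post_len <- chrom_len - cds_start + 1L - nchar(cds_seq)
  post <- paste(rep("A", post_len), collapse = "")
  seq_fwd <- if (strand == "+") cds_seq else
    paste(rev(c(A = "T", T = "A", C = "G", G = "C")[
      strsplit(cds_seq, "")[[1]]]), collapse = "")
  ref_seqs <- c(chr1 = paste0(pre, seq_fwd, post))
  cds_end <- cds_start + nchar(cds_seq) - 1L
  gene <- list(gene_id = "g1", chrom = "chr1",
               start = max(1L, cds_start - 50L),
               end = min(chrom_len, cds_end + 50L), strand = strand,
               cds = data.frame(start = cds_start, end = cds_end,
                                phase = 0L),
               exons = data.frame(start = cds_start, end = cds_end))
  list(gene = gene, ref_seqs = ref_seqs,
       cds_start = cds_start, cds_end = cds_end)
}
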