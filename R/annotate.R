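ANNOTATION_CATEGORIES <- c("intergenic", "upstream", "downstream", "intron",
                           "exon_synonymous", "exon_missense", "exon_other")

#' Assign SNPs to genes within a window
#'
#' A gene is assigned to a SNP iff its span intersects
#' `[pos - window, pos + window]`; the rule is inclusive at exactly
#' `window` bp and all overlapping genes are reported (the mapping is
#' many-to-many). Distance is 0 for a SNP inside the gene span, else the
#' gap to the nearest span edge.
#'
#' @param snps data.frame with `chrom` and `pos` (1-based).
#' @param genes list of gene models (see [read_gff3_genes()]).
#' @param window flank size in bp (default 50000).
#' @return data.frame with `snp_index`, `gene_id`, `distance`.
#' @export
assign_genes <- function(snps, genes, window = 50000L) {
  if (window < 0) .fail("assign_genes: window must be >= 0")
  if (nrow(snps) == 0L || length(genes) == 0L)
    return(data.frame(snp_index = integer(), gene_id = character(),
                      distance = integer()))
  gstart <- vapply(genes, `[[`, numeric(1), "start")
  gend <- vapply(genes, `[[`, numeric(1), "end")
  gchrom <- vapply(genes, `[[`, character(1), "chrom")
  gid <- vapply(genes, `[[`, character(1), "gene_id")
  gene_gr <- GenomicRanges::GRanges(gchrom, IRanges::IRanges(gstart, gend))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr,
                                      maxgap = max(window - 1L, -1L))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- ifelse(snps$pos[qi] < gstart[si], gstart[si] - snps$pos[qi],
              ifelse(snps$pos[qi] > gend[si], snps$pos[qi] - gend[si], 0L))
  out <- data.frame(snp_index = qi, gene_id = gid[si],
                    distance = as.integer(d), stringsAsFactors = FALSE)
  out[order(out$snp_index, out$distance, out$gene_id), , drop = FALSE]
}

# complement / reverse-complement for plain character bases
.comp <- c(A = "T", T = "A", C = "G", G = "C", N = "N")
revcomp_chr <- function(s) {
  paste(rev(.comp[strsplit(s, "")[[1]]]), collapse = "")
}

# classify a single-base substitution inside a CDS of gene `g`;
# returns "exon_synonymous", "exon_missense" or "exon_other"
classify_cds_change <- function(g, pos, ref, alt, ref_seqs) {
  chrom_seq <- ref_seqs[[g$chrom]]
  if (is.null(chrom_seq)) return("exon_other")
  cds <- g$cds
  pieces <- substring(chrom_seq, cds$start, cds$end)
  cds_seq <- paste(pieces, collapse = "")
  # 0-based offset of pos in the genomically concatenated CDS
  lens <- cds$end - cds$start + 1L
  before <- cumsum(c(0L, lens))[seq_len(nrow(cds))]
  k <- which(pos >= cds$start & pos <= cds$end)
  if (length(k) != 1L) return("exon_other")
  g_off <- before[k] + (pos - cds$start[k])
  if (g$strand == "-") {
    cds_seq <- revcomp_chr(cds_seq)
    off <- nchar(cds_seq) - 1L - g_off
    ref <- unname(.comp[ref]); alt <- unname(.comp[alt])
  } else {
    off <- g_off
  }
  if (nchar(cds_seq) %% 3 != 0) return("exon_other")
  codon_i <- off %/% 3L
  in_codon <- off %% 3L + 1L
  codon <- substr(cds_seq, 3L * codon_i + 1L, 3L * codon_i + 3L)
  if (nchar(codon) != 3L) return("exon_other")
  ref_codon <- codon; alt_codon <- codon
  substr(ref_codon, in_codon, in_codon) <- ref
  substr(alt_codon, in_codon, in_codon) <- alt
  if (grepl("[^ACGT]", ref_codon) || grepl("[^ACGT]", alt_codon))
    return("exon_other")
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[ref_codon]); aa_alt <- unname(gc[alt_codon])
  if (aa_ref == aa_alt) return("exon_synonymous")
  if (aa_ref != "*" && aa_alt != "*") return("exon_missense")
  "exon_other"  # stop gain/loss kept out of the missense tally
}

#' Categorize one SNP against gene models
#'
#' Precedence when several features overlap: CDS (synonymous / missense /
#' other by strand-aware codon substitution under the standard genetic
#' code) > non-coding exon (`exon_other`) > intron > upstream /
#' downstream of the nearest gene (5' side = upstream, respecting
#' strand) > intergenic. Without reference sequence, CDS/exon hits stop
#' at `exon_other`.
#'
#' @param chrom,pos,ref,alt the SNP.
#' @param genes list of gene models.
#' @param ref_seqs named list/vector of chromosome sequences (plain
#'   character), or NULL.
#' @param window flank in bp for upstream/downstream assignment.
#' @return list with `category`, `gene_ids` (character vector, empty iff
#'   intergenic) and `distance` (bp to nearest assigned gene).
#' @export
categorize_snp <- function(chrom, pos, ref, alt, genes, ref_seqs = NULL,
                           window = 50000L) {
  sel <- vapply(genes, function(g) g$chrom == chrom, logical(1))
  gs <- genes[sel]
  if (length(gs) == 0L)
    return(list(category = "intergenic", gene_ids = character(),
                distance = NA_integer_))
  dist <- vapply(gs, function(g) {
    if (pos < g$start) g$start - pos
    else if (pos > g$end) pos - g$end
    else 0L
  }, numeric(1))
  assigned <- which(dist <= window)
  if (length(assigned) == 0L)
    return(list(category = "intergenic", gene_ids = character(),
                distance = NA_integer_))
  gene_ids <- vapply(gs[assigned], `[[`, character(1), "gene_id")
  inside <- assigned[dist[assigned] == 0]
  category <- NULL
  for (i in inside) {
    g <- gs[[i]]
    in_cds <- nrow(g$cds) > 0 && any(pos >= g$cds$start & pos <= g$cds$end)
    if (in_cds) {
      category <- if (is.null(ref_seqs)) "exon_other" else
        classify_cds_change(g, pos, ref, alt, ref_seqs)
      break
    }
  }
  if (is.null(category)) {
    for (i in inside) {
      g <- gs[[i]]
      if (nrow(g$exons) > 0 && any(pos >= g$exons$start & pos <= g$exons$end)) {
        category <- "exon_other"
        break
      }
    }
  }
  if (is.null(category) && length(inside)) category <- "intron"
  if (is.null(category)) {
    near <- assigned[which.min(dist[assigned])]
    g <- gs[[near]]
    before <- pos < g$start
    category <- if ((before && g$strand != "-") || (!before && g$strand == "-"))
      "upstream" else "downstream"
  }
  list(category = category, gene_ids = unname(gene_ids),
       distance = as.integer(min(dist[assigned])))
}

#' Annotate a candidate SNP table
#'
#' Applies [categorize_snp()] to every row; chromosomes absent from the
#' gene set trigger one warning each.
#'
#' @param candidates data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param genes list of gene models.
#' @param ref_seqs optional named chromosome sequences.
#' @param window flank in bp (default 50000).
#' @return data.frame: the input plus `category`, `gene_ids`
#'   (comma-separated), `n_genes`, `distance`.
#' @export
annotate_candidates <- function(candidates, genes, ref_seqs = NULL,
                                window = 50000L) {
  gene_chroms <- unique(vapply(genes, `[[`, character(1), "chrom"))
  missing_chroms <- setdiff(unique(candidates$chrom), gene_chroms)
  for (ch in missing_chroms)
    warning(sprintf("no gene models on chromosome %s; SNPs there are intergenic",
                    ch))
  ann <- lapply(seq_len(nrow(candidates)), function(i) {
    categorize_snp(candidates$chrom[i], candidates$pos[i],
                   candidates$ref[i], candidates$alt[i],
                   genes, ref_seqs, window)
  })
  candidates$category <- vapply(ann, `[[`, character(1), "category")
  candidates$gene_ids <- vapply(ann, function(a)
    paste(a$gene_ids, collapse = ","), character(1))
  candidates$n_genes <- vapply(ann, function(a) length(a$gene_ids), integer(1))
  candidates$distance <- vapply(ann, `[[`, integer(1), "distance")
  candidates
}

#' Count annotations per category
#'
#' @param annotations data.frame with a `category` column.
#' @return data.frame `category`, `n` over all categories (zeros kept);
#'   `sum(n)` equals the number of input SNPs.
#' @export
annotation_summary <- function(annotations) {
  tab <- table(factor(annotations$category, levels = ANNOTATION_CATEGORIES))
  data.frame(category = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
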