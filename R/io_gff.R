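#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (via \pkg{rtracklayer}) into a list
#' of gene models. Coordinates are 1-based inclusive throughout. When a
#' gene has several transcripts the one with the longest total CDS is
#' retained for codon-level categorization.
#'
#' Each gene model is a list with fields `gene_id`, `chrom`, `start`,
#' `end`, `strand`, `cds` (data.frame `start`, `end`, `phase`, sorted by
#' genomic start) and `exons` (data.frame `start`, `end`).
#'
#' @param path GFF3 file path.
#' @return list of gene models, ordered by chromosome then start.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  df$Parent <- if ("Parent" %in% names(df))
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  else NA_character_
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) return(list())
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx2gene <- setNames(tx$Parent, tx$ID)
  parent_gene <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% genes$ID) p else unname(tx2gene[p])
  }
  sub <- df[df$type %in% c("CDS", "exon"), , drop = FALSE]
  sub$gene <- vapply(sub$Parent, parent_gene, character(1))
  sub$tx <- ifelse(sub$Parent %in% genes$ID, NA_character_, sub$Parent)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    feat <- sub[!is.na(sub$gene) & sub$gene == g$ID, , drop = FALSE]
    cds <- feat[feat$type == "CDS", , drop = FALSE]
    if (nrow(cds) && any(!is.na(cds$tx))) {
      len_by_tx <- tapply(cds$end - cds$start + 1L, cds$tx, sum)
      best <- names(len_by_tx)[which.max(len_by_tx)]
      cds <- cds[is.na(cds$tx) | cds$tx == best, , drop = FALSE]
    }
    if (nrow(cds) && (any(cds$start < g$start) || any(cds$end > g$end)))
      .fail("gene %s: CDS outside gene span", g$ID)
    cds <- cds[order(cds$start), , drop = FALSE]
    if (nrow(cds) > 1L && any(cds$start[-1] <= cds$end[-nrow(cds)]))
      .fail("gene %s: overlapping CDS intervals", g$ID)
    exons <- feat[feat$type == "exon", , drop = FALSE]
    exons <- exons[order(exons$start), , drop = FALSE]
    phase <- if ("phase" %in% names(cds) && nrow(cds)) {
      ph <- suppressWarnings(as.integer(as.character(cds$phase)))
      ifelse(is.na(ph), 0L, ph)
    } else integer(nrow(cds))
    list(gene_id = g$ID,
         chrom = as.character(g$seqnames),
         start = g$start, end = g$end,
         strand = as.character(g$strand),
         cds = data.frame(start = cds$start, end = cds$end, phase = phase),
         exons = unique(data.frame(start = exons$start, end = exons$end)))
  })
  ord <- order(vapply(out, `[[`, character(1), "chrom"),
               vapply(out, `[[`, numeric(1), "start"))
  out[ord]
}

#' Write gene models as GFF3
#'
#' Minimal GFF3 serializer for gene models produced by [read_gff3_genes()]
#' or the synthetic generator; round-trips through [read_gff3_genes()].
#'
#' @param genes list of gene models.
#' @param path output path.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, sprintf("%s\tpoolrfi\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, g$start, g$end, g$strand, g$gene_id))
    mrna <- paste0(g$gene_id, ".t1")
    lines <- c(lines, sprintf("%s\tpoolrfi\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                              g$chrom, g$start, g$end, g$strand, mrna, g$gene_id))
    if (nrow(g$exons))
      lines <- c(lines, sprintf("%s\tpoolrfi\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                g$chrom, g$exons$start, g$exons$end, g$strand, mrna))
    if (nrow(g$cds))
      lines <- c(lines, sprintf("%s\tpoolrfi\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                                g$chrom, g$cds$start, g$cds$end, g$strand,
                                g$cds$phase, mrna, mrna))
  }
  writeLines(lines, path)
  invisible(path)
}
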