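#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt_i = dCt_i - mean(dCt of the reference group)` and
#' `rel_expr_i = 2^-ddCt_i`. By construction the geometric mean of
#' `rel_expr` in the reference group is exactly 1. Samples with a missing
#' reference-gene Ct are dropped and counted.
#'
#' @param ct Ct table (see [read_ct_table()]): `sample_id`, `group`,
#'   `gene`, `ct_target`, `ct_reference`.
#' @param reference_group group used as the calibrator (default "HRFI").
#' @return list with `samples` (per-sample `delta_ct`, `ddct`,
#'   `rel_expr`), `genes` (per gene x group: mean and SD of `rel_expr`
#'   and of `delta_ct`, fold change vs the reference group) and
#'   `n_dropped`.
#' @export
ddct <- function(ct, reference_group = "HRFI") {
  if (!reference_group %in% ct$group)
    .fail("ddct: reference group '%s' absent", reference_group)
  drop <- is.na(ct$ct_reference) | is.na(ct$ct_target)
  n_dropped <- sum(drop)
  ct <- ct[!drop, , drop = FALSE]
  ct$delta_ct <- ct$ct_target - ct$ct_reference
  out <- lapply(split(ct, ct$gene), function(d) {
    if (any(table(d$group) < 2L))
      .fail("ddct: gene %s has < 2 samples in a group", d$gene[1])
    ref_mean <- mean(d$delta_ct[d$group == reference_group])
    d$ddct <- d$delta_ct - ref_mean
    d$rel_expr <- 2^(-d$ddct)
    d
  })
  samples <- do.call(rbind, out)
  rownames(samples) <- NULL
  genes <- do.call(rbind, lapply(out, function(d) {
    agg <- lapply(split(d, d$group), function(g)
      data.frame(gene = g$gene[1], group = g$group[1],
                 n = nrow(g),
                 rel_expr_mean = mean(g$rel_expr),
                 rel_expr_sd = sd(g$rel_expr),
                 delta_ct_mean = mean(g$delta_ct),
                 delta_ct_sd = sd(g$delta_ct),
                 stringsAsFactors = FALSE))
    do.call(rbind, agg)
  }))
  rownames(genes) <- NULL
  ref_rows <- genes[genes$group == reference_group, c("gene", "delta_ct_mean")]
  genes$fold_vs_reference <-
    2^(-(genes$delta_ct_mean -
           ref_rows$delta_ct_mean[match(genes$gene, ref_rows$gene)]))
  list(samples = samples, genes = genes, n_dropped = n_dropped)
}

#' Two-group Student's t-test per gene on the dCt scale
#'
#' Equal-variance two-sample t on `delta_ct` (the log2 scale, where
#' normality is the defensible assumption); identical groups give p = 1.
#' Stars: `*` p < 0.05, `**` p < 0.01.
#'
#' @param samples per-sample table from [ddct()] (needs `gene`, `group`,
#'   `delta_ct`).
#' @return data.frame: `gene`, `t_stat`, `p_value`, `stars`.
#' @export
group_ttest <- function(samples) {
  out <- lapply(split(samples, samples$gene), function(d) {
    gr <- unique(d$group)
    if (length(gr) != 2L) .fail("group_ttest: gene %s needs two groups",
                                d$gene[1])
    a <- d$delta_ct[d$group == gr[1]]
    b <- d$delta_ct[d$group == gr[2]]
    if (length(a) < 2L || length(b) < 2L)
      .fail("group_ttest: >= 2 samples per group required")
    if (sd(c(a, b)) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
    }
    data.frame(gene = d$gene[1], t_stat = unname(tt$statistic),
               p_value = tt$p.value,
               stars = if (tt$p.value < 0.01) "**"
               else if (tt$p.value < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
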