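#' Screen configuration
#'
#' Tuning parameters of the pooled SNP screen.
#'
#' @param min_coverage minimum usable reads (ref + alt) required in every
#'   pool; sites below are excluded (default 4).
#' @param max_coverage_quantile sites where any pool exceeds this quantile
#'   of the pooled coverage distribution are excluded as repeat-region
#'   suspects (default 0.99; set to 1 to disable).
#' @param fst_top_fraction fraction of scored sites kept by the F_ST rank
#'   filter (default 0.05, i.e. top 5%).
#' @param delta_mode `"median_of_top"` derives the allele-frequency
#'   divergence cutoff as the median divergence within the F_ST top set
#'   (the default, mirroring a data-derived 35% rule);
#'   `"fixed"` uses `delta_fixed`.
#' @param delta_fixed fixed divergence cutoff (default 0.35).
#' @param q_cutoff BH-adjusted p-value cutoff (default 0.05).
#' @param fst_method pooled F_ST estimator, `"pi"` (classical
#'   heterozygosity-based, default) or `"karlsson"`.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(min_coverage = 4L, max_coverage_quantile = 0.99,
                          fst_top_fraction = 0.05,
                          delta_mode = c("median_of_top", "fixed"),
                          delta_fixed = 0.35, q_cutoff = 0.05,
                          fst_method = c("pi", "karlsson")) {
  delta_mode <- match.arg(delta_mode)
  fst_method <- match.arg(fst_method)
  if (fst_top_fraction <= 0 || fst_top_fraction > 1)
    .fail("screen_config: fst_top_fraction must be in (0, 1]")
  if (delta_fixed < 0 || delta_fixed > 1)
    .fail("screen_config: delta_fixed must be in [0, 1]")
  structure(list(min_coverage = min_coverage,
                 max_coverage_quantile = max_coverage_quantile,
                 fst_top_fraction = fst_top_fraction,
                 delta_mode = delta_mode, delta_fixed = delta_fixed,
                 q_cutoff = q_cutoff, fst_method = fst_method),
            class = "screen_config")
}

#' Per-pool alternate-allele frequencies
#'
#' Frequency = alt / (ref + alt) per pool. A site is usable only when
#' every pool has coverage within `[min_coverage, cap]`, where the cap is
#' the `max_coverage_quantile` quantile of all pool coverages.
#'
#' @param ref_counts,alt_counts site x pool count matrices (from
#'   [biallelic_reduce()]).
#' @param config a [screen_config()].
#' @return list with `freq` (site x pool), `coverage` (site x pool),
#'   `usable` (logical per site) and exclusion counts.
#' @export
pool_frequencies <- function(ref_counts, alt_counts,
                             config = screen_config()) {
  cov <- ref_counts + alt_counts
  cap <- if (config$max_coverage_quantile >= 1) Inf else
    quantile(cov, config$max_coverage_quantile, names = FALSE)
  low <- apply(cov < config$min_coverage, 1, any)
  high <- apply(cov > cap, 1, any)
  freq <- alt_counts / ifelse(cov > 0, cov, NA_real_)
  list(freq = freq, coverage = cov, usable = !(low | high),
       n_excluded_low_coverage = sum(low),
       n_excluded_high_coverage = sum(high & !low))
}

#' One-way ANOVA of pool frequencies between groups
#'
#' Observational units are the replicate pools; the factor is the
#' phenotypic group. F has df (1, n_pools - 2). Sites with zero between-
#' and within-group variance are degenerate and get p = 1 by convention.
#' Vectorized over sites.
#'
#' @param freq site x pool frequency matrix (or a vector for one site).
#' @param groups factor/character of length n_pools.
#' @return data.frame with `F_stat`, `p_value`, `degenerate`.
#' @export
anova_screen <- function(freq, groups) {
  if (is.vector(freq)) freq <- matrix(freq, nrow = 1)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) .fail("anova_screen: exactly two groups required")
  n1 <- sum(groups == lv[1]); n2 <- sum(groups == lv[2])
  if (n1 < 2L || n2 < 2L) .fail("anova_screen: >= 2 replicates per group")
  n <- n1 + n2
  m1 <- rowMeans(freq[, groups == lv[1], drop = FALSE])
  m2 <- rowMeans(freq[, groups == lv[2], drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  sst <- rowSums((freq - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  df2 <- n - 2L
  F_stat <- (ssb / 1) / (ssw / df2)
  degenerate <- ssw == 0 & ssb == 0
  F_stat[degenerate] <- 0
  p <- pf(F_stat, 1, df2, lower.tail = FALSE)
  p[degenerate] <- 1
  data.frame(F_stat = F_stat, p_value = p, degenerate = degenerate)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min over j with p_j >= p_i of (m p_j / rank_j)`, clamped to 1;
#' monotone in p and invariant to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    .fail("benjamini_hochberg: p-values outside [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Pooled F_ST between the two phenotypic groups
#'
#' Classical heterozygosity-based pool-seq estimator. Read counts are
#' first aggregated over each group's replicate pools; for group g with
#' aggregated alt frequency p_g, read coverage c_g and n_g pooled diploid
#' individuals, `C_g = min(c_g, 2 n_g)` and
#' `pi_g = C_g / (C_g - 1) * 2 p_g (1 - p_g)`. The total `pi_T` uses the
#' combined counts and `C_T = min(c_L + c_H, 2 n_L + 2 n_H)`. Then
#' `F_ST = max(0, (pi_T - (pi_L + pi_H) / 2) / pi_T)`, 0 when `pi_T = 0`
#' (monomorphic; flagged). The `"karlsson"` option implements the
#' two-population unbiased-numerator estimator
#' `N = (p_L - p_H)^2 - h_L / c_L - h_H / c_H`, `D = N + h_L + h_H` with
#' `h_g = c_g / (c_g - 1) * p_g (1 - p_g)`, clamped to \[0, 1\].
#'
#' @param ref_counts,alt_counts site x pool count matrices.
#' @param groups group label per pool.
#' @param n_ind diploid individuals per pool (scalar or per-pool vector).
#' @param method `"pi"` or `"karlsson"`.
#' @return data.frame with `fst` and `monomorphic` flag.
#' @export
pooled_fst <- function(ref_counts, alt_counts, groups, n_ind = 16L,
                       method = c("pi", "karlsson")) {
  method <- match.arg(method)
  if (is.vector(ref_counts)) ref_counts <- matrix(ref_counts, nrow = 1)
  if (is.vector(alt_counts)) alt_counts <- matrix(alt_counts, nrow = 1)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) .fail("pooled_fst: exactly two groups required")
  n_ind <- rep_len(n_ind, length(groups))
  agg <- function(g) {
    sel <- groups == g
    list(ref = rowSums(ref_counts[, sel, drop = FALSE]),
         alt = rowSums(alt_counts[, sel, drop = FALSE]),
         chroms = 2 * sum(n_ind[sel]))
  }
  g1 <- agg(lv[1]); g2 <- agg(lv[2])
  c1 <- g1$ref + g1$alt; c2 <- g2$ref + g2$alt
  p1 <- ifelse(c1 > 0, g1$alt / c1, NA_real_)
  p2 <- ifelse(c2 > 0, g2$alt / c2, NA_real_)
  if (method == "pi") {
    corr_pi <- function(p, cc, chroms) {
      C <- pmin(cc, chroms)
      ifelse(C > 1, C / (C - 1) * 2 * p * (1 - p), 0)
    }
    pi1 <- corr_pi(p1, c1, g1$chroms)
    pi2 <- corr_pi(p2, c2, g2$chroms)
    pt <- (g1$alt + g2$alt) / (c1 + c2)
    piT <- corr_pi(pt, c1 + c2, g1$chroms + g2$chroms)
    fst <- ifelse(piT > 0, pmax(0, (piT - (pi1 + pi2) / 2) / piT), 0)
    mono <- piT == 0
  } else {
    h1 <- ifelse(c1 > 1, c1 / (c1 - 1) * p1 * (1 - p1), 0)
    h2 <- ifelse(c2 > 1, c2 / (c2 - 1) * p2 * (1 - p2), 0)
    N <- (p1 - p2)^2 - h1 / c1 - h2 / c2
    D <- N + h1 + h2
    fst <- ifelse(D > 0, pmin(1, pmax(0, N / D)), 0)
    mono <- D <= 0
  }
  data.frame(fst = fst, monomorphic = mono)
}

#' Run the full pooled screen on a sync object
#'
#' Chains biallelic reduction, coverage filtering, per-pool frequencies,
#' replicate ANOVA with BH adjustment, pooled F_ST and the candidate
#' filter cascade.
#'
#' @param sync a `pool_sync` object.
#' @param config a [screen_config()].
#' @return list of class `screen_output` with `results` (one row per
#'   scored site: positions, per-group mean frequencies, `delta_p`,
#'   `F_stat`, `p_value`, `q_value`, `fst`, `fst_rank_pct`, filter flags,
#'   `candidate`) and `report` (exclusion tallies and derived
#'   thresholds).
#' @export
screen_sites <- function(sync, config = screen_config()) {
  stopifnot(inherits(sync, "pool_sync"))
  bi <- biallelic_reduce(sync)
  pf_ <- pool_frequencies(bi$ref_counts, bi$alt_counts, config)
  use <- bi$keep & pf_$usable
  groups <- sync$layout$group
  res <- data.frame(chrom = sync$sites$chrom[use],
                    pos = sync$sites$pos[use],
                    ref = sync$sites$ref[use],
                    alt = bi$alt[use],
                    stringsAsFactors = FALSE)
  freq <- pf_$freq[use, , drop = FALSE]
  lv <- unique(groups)
  res$p_low <- rowMeans(freq[, groups == lv[1], drop = FALSE])
  res$p_high <- rowMeans(freq[, groups == lv[2], drop = FALSE])
  res$delta_p <- abs(res$p_low - res$p_high)
  av <- anova_screen(freq, groups)
  res$F_stat <- av$F_stat
  res$p_value <- av$p_value
  res$degenerate <- av$degenerate
  res$q_value <- benjamini_hochberg(res$p_value)
  fs <- pooled_fst(bi$ref_counts[use, , drop = FALSE],
                   bi$alt_counts[use, , drop = FALSE],
                   groups, sync$layout$n_ind, method = config$fst_method)
  res$fst <- fs$fst
  res$monomorphic <- fs$monomorphic
  out <- filter_cascade(res, config)
  out$report$n_sites_in <- nrow(sync$sites)
  out$report$n_excluded_triallelic <- bi$n_excluded_triallelic
  out$report$n_excluded_low_coverage <- pf_$n_excluded_low_coverage
  out$report$n_excluded_high_coverage <- pf_$n_excluded_high_coverage
  out$report$n_scored <- nrow(res)
  structure(out, class = "screen_output")
}

#' Candidate filter cascade
#'
#' Flags computed per scored site:
#' * `passed_anova`: BH-adjusted q < `q_cutoff`;
#' * `in_top_fst`: F_ST at or above the `1 - fst_top_fraction` quantile of
#'   all scored sites (boundary ties kept inclusively);
#' * `passed_delta`: allele-frequency divergence above the threshold
#'   `delta_star` (median divergence within the F_ST top set, or the
#'   fixed value).
#'
#' A site is a `candidate` when all three hold. The F_ST rank and the
#' divergence threshold are computed over all scored sites, not only the
#' ANOVA survivors: the published top-5% counts are whole-set tallies,
#' and a survivor-only denominator would make the rank filter collapse
#' when few sites pass the ANOVA. The report records both thresholds and
#' the count surviving each cumulative step.
#'
#' @param results scored-site data.frame (from [screen_sites()]).
#' @param config a [screen_config()].
#' @return list with `results` (flags appended) and `report`.
#' @export
filter_cascade <- function(results, config = screen_config()) {
  n <- nrow(results)
  if (n == 0L) {
    return(list(results = results,
                report = list(fst_threshold = NA_real_,
                              delta_star = NA_real_,
                              n_pass_anova = 0L, n_pass_fst = 0L,
                              n_candidates = 0L)))
  }
  results$fst_rank_pct <- rank(results$fst, ties.method = "max") / n
  fst_thr <- quantile(results$fst, 1 - config$fst_top_fraction,
                      names = FALSE, type = 7)
  in_top <- results$fst >= fst_thr
  delta_star <- if (config$delta_mode == "fixed") config$delta_fixed else
    median(results$delta_p[in_top])
  results$passed_anova <- results$q_value < config$q_cutoff
  results$in_top_fst <- in_top
  results$passed_delta <- results$delta_p > delta_star
  results$candidate <- results$passed_anova & results$in_top_fst &
    results$passed_delta
  report <- list(
    fst_threshold = fst_thr,
    delta_star = delta_star,
    n_pass_anova = sum(results$passed_anova),
    n_pass_fst = sum(results$passed_anova & results$in_top_fst),
    n_candidates = sum(results$candidate),
    n_top_fst_ties = sum(results$fst == fst_thr))
  list(results = results, report = report)
}

#' Candidate counts per chromosome
#'
#' @param candidates data.frame with a `chrom` column (e.g. the candidate
#'   subset of screen results).
#' @return data.frame `chrom`, `n`, natural-sorted by chromosome.
#' @export
per_chromosome_counts <- function(candidates) {
  if (nrow(candidates) == 0L)
    return(data.frame(chrom = character(), n = integer()))
  tab <- table(candidates$chrom)
  out <- data.frame(chrom = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[match(natural_sort(out$chrom), out$chrom), , drop = FALSE]
}

#' @export
print.screen_output <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "pooled screen: %d sites in, %d scored\n",
    "  excluded: %d triallelic/invalid-ref, %d low-coverage, %d high-coverage\n",
    "  q < cutoff: %d; + F_ST top set: %d; + delta_p > %.3f: %d candidates\n"),
    r$n_sites_in, r$n_scored, r$n_excluded_triallelic,
    r$n_excluded_low_coverage, r$n_excluded_high_coverage,
    r$n_pass_anova, r$n_pass_fst, r$delta_star, r$n_candidates))
  invisible(x)
}
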