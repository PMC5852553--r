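test_that("pool_frequencies computes alt fractions and enforces coverage", {
  ref <- rbind(c(16, 10), c(0, 5), c(2, 30))
  alt <- rbind(c(4, 10), c(20, 5), c(1, 10))
  pf <- pool_frequencies(ref, alt, screen_config(min_coverage = 4,
                                                 max_coverage_quantile = 1))
  expect_equal(pf$freq[1, 1], 0.2)
  expect_equal(pf$freq[2, 1], 1.0)
  expect_false(pf$usable[3])  # pool 1 coverage 3 < 4
  expect_equal(pf$n_excluded_low_coverage, 1L)
})

test_that("anova_screen handles degenerate, separated and random inputs", {
  g <- rep(c("L", "H"), each = 3)
  a1 <- anova_screen(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), g)
  expect_equal(a1$F_stat, 0)
  expect_equal(a1$p_value, 1)

  a2 <- anova_screen(c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9), g)
  expect_lt(a2$p_value, 1e-6)

  # oracle: stats::aov sum-of-squares decomposition, 100 random sites
  set.seed(31)
  freq <- matrix(runif(600), ncol = 6)
  got <- anova_screen(freq, g)
  for (i in seq_len(100)) {
    sm <- summary(aov(freq[i, ] ~ factor(g)))[[1]]
    expect_equal(got$F_stat[i], sm$`F value`[1], tolerance = 1e-8)
    expect_equal(got$p_value[i], sm$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("benjamini_hochberg reproduces the step-up formula and p.adjust", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "outside")

  set.seed(17)
  for (k in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- benjamini_hochberg(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    # monotone in p, order-invariant
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    perm <- sample(seq_along(p))
    expect_equal(benjamini_hochberg(p[perm]), q[perm])
  }
})

test_that("pooled_fst: zero at equality, ~1 at fixation, matches the direct formula", {
  g <- rep(c("L", "H"), each = 3)
  same <- pooled_fst(matrix(10, 1, 6), matrix(10, 1, 6), g, n_ind = 16)
  expect_equal(same$fst, 0)

  # fixed difference, 48 chromosomes per group (3 pools of 8 diploids)
  fixed <- pooled_fst(matrix(rep(c(1000, 0), each = 3), 1, 6),
                      matrix(rep(c(0, 1000), each = 3), 1, 6),
                      g, n_ind = 8)
  expect_gte(fixed$fst, 0.97)

  set.seed(23)
  for (k in 1:100) {
    ref <- matrix(rpois(6, 20), 1, 6)
    alt <- matrix(rpois(6, 8), 1, 6)
    got <- pooled_fst(ref, alt, g, n_ind = 16)$fst
    want <- oracle_pooled_fst(sum(ref[1, 1:3]), sum(alt[1, 1:3]),
                              sum(ref[1, 4:6]), sum(alt[1, 4:6]),
                              chrom1 = 2 * 48, chrom2 = 2 * 48)
    expect_equal(got, want, tolerance = 1e-8)
    # allele-label swap invariance
    swapped <- pooled_fst(alt, ref, g, n_ind = 16)$fst
    expect_equal(got, swapped, tolerance = 1e-12)
  }
})

test_that("karlsson estimator stays in [0,1], is label-swap invariant, zero at equality", {
  g <- rep(c("L", "H"), each = 3)
  expect_equal(pooled_fst(matrix(10, 1, 6), matrix(10, 1, 6), g,
                          method = "karlsson")$fst, 0)
  set.seed(5)
  ref <- matrix(rpois(60, 15), 10, 6)
  alt <- matrix(rpois(60, 10), 10, 6)
  a <- pooled_fst(ref, alt, g, method = "karlsson")$fst
  b <- pooled_fst(alt, ref, g, method = "karlsson")$fst
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("filter_cascade: no-op configuration keeps everything, flags nest", {
  set.seed(41)
  n <- 200
  res <- data.frame(chrom = "chr1", pos = seq_len(n),
                    delta_p = runif(n, 0.01, 0.9),
                    q_value = runif(n), fst = runif(n))
  noop <- filter_cascade(res, screen_config(fst_top_fraction = 1,
                                            delta_mode = "fixed",
                                            delta_fixed = 0, q_cutoff = 1))
  expect_true(all(noop$results$candidate))

  cc <- filter_cascade(res, screen_config())
  r <- cc$results
  expect_true(all(r$candidate <= (r$passed_anova & r$in_top_fst &
                                    r$passed_delta)))
  expect_equal(cc$report$n_candidates, sum(r$candidate))
  expect_equal(cc$report$delta_star, median(r$delta_p[r$in_top_fst]))
})

test_that("filter_cascade keeps all ties at the F_ST boundary", {
  res <- data.frame(chrom = "chr1", pos = 1:100,
                    delta_p = rep(0.5, 100), q_value = rep(0.001, 100),
                    fst = c(rep(0.9, 8), rep(0.1, 92)))
  cc <- filter_cascade(res, screen_config(fst_top_fraction = 0.05,
                                          delta_mode = "fixed",
                                          delta_fixed = 0.35))
  # 8 tied sites straddle the 5% boundary: all retained
  expect_equal(sum(cc$results$in_top_fst), 8L)
  expect_gte(cc$report$n_top_fst_ties, 8L)
})

test_that("screen has power when divergent loci are dense enough for BH to adapt", {
  # 50 planted loci of 1000 with a fixed 0.35 divergence cutoff: in this
  # regime the BH threshold adapts to the non-null mass and the full
  # three-flag cascade recovers nearly all planted loci. (At 5/10,000
  # planted the BH step is unpassable with df (1, 4) ANOVA p-values: see
  # the methods vignette.)
  rates <- vapply(1:5, function(k) {
    cfg <- sim_config(seed = 3000 + k, n_snps = 1000, n_divergent = 50,
                      delta_p_planted = 0.8)
    pc <- simulate_pool_counts(cfg)
    sc <- screen_sites(pc$sync,
                       screen_config(delta_mode = "fixed",
                                     delta_fixed = 0.35,
                                     max_coverage_quantile = 1))
    key <- paste(pc$sync$sites$chrom, pc$sync$sites$pos)[pc$truth$divergent]
    idx <- match(key, paste(sc$results$chrom, sc$results$pos))
    mean(sc$results$candidate[idx], na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(rates), 0.9)
})

test_that("a single strongly planted locus always tops the F_ST and delta filters", {
  for (k in 1:5) {
    cfg <- sim_config(seed = 4000 + k, n_snps = 500, n_divergent = 1,
                      delta_p_planted = 0.8)
    pc <- simulate_pool_counts(cfg)
    sc <- screen_sites(pc$sync, screen_config(max_coverage_quantile = 1))
    key <- paste(pc$sync$sites$chrom, pc$sync$sites$pos)[pc$truth$divergent]
    idx <- match(key, paste(sc$results$chrom, sc$results$pos))
    expect_true(sc$results$in_top_fst[idx])
    expect_true(sc$results$passed_delta[idx])
  }
})

test_that("null screen stays calibrated: BH-significant fraction near alpha", {
  cfg <- sim_config(seed = 19, n_snps = 4000, n_divergent = 0)
  sc <- screen_sites(simulate_pool_counts(cfg)$sync)
  m <- nrow(sc$results)
  frac <- mean(sc$results$q_value < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / m))
})

test_that("per_chromosome_counts tallies and natural-sorts", {
  cand <- data.frame(chrom = c("chr1", "chr2", "chr1", "chr10", "chr1"))
  pc <- per_chromosome_counts(cand)
  expect_equal(pc$chrom, c("chr1", "chr2", "chr10"))
  expect_equal(pc$n, c(3L, 1L, 1L))
  expect_equal(nrow(per_chromosome_counts(cand[0, , drop = FALSE])), 0L)
})
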