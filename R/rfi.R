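#' Fit the RFI regression and derive per-bird traits
#'
#' Residual feed intake is the residual of the ordinary least-squares
#' regression of total feed intake on metabolic body weight and weight
#' gain: `FI = b0 + b1 BW^0.75 + b2 WG + rfi`. Derived traits filled in:
#' `wg` (g), `adg` (g/d), `dfi` (g/d), `mbw` (g^0.75, on initial body
#' weight), `rfi` (g) and `fcr` (= dfi/adg, per bird).
#'
#' @param records phenotype data.frame (see [read_phenotypes()] for the
#'   required columns).
#' @param by_sex fit separate regressions per sex (off by default; one
#'   pooled fit is the standard reading for a mixed-sex flock).
#' @return list with `fit` (class `rfi_fit`: `b0`, `b1`, `b2`,
#'   `residual_sd`, `r_squared`, `n`; one per sex when `by_sex`) and
#'   `records` with derived columns appended.
#' @examples
#' cfg <- sim_config(seed = 1, n_birds = 50)
#' ph <- simulate_phenotypes(cfg)$phenotypes
#' fit_rfi(ph)$fit
#' @export
fit_rfi <- function(records, by_sex = FALSE) {
  if (nrow(records) < 3L) .fail("fit_rfi: need >= 3 records")
  records$wg <- records$final_bw - records$initial_bw
  records$adg <- records$wg / records$test_days
  records$dfi <- records$total_fi / records$test_days
  records$mbw <- records$initial_bw^0.75
  one_fit <- function(d) {
    X <- cbind(1, d$mbw, d$wg)
    qx <- qr(X)
    if (qx$rank < 3L) {
      cols <- c("(intercept)", "mbw", "wg")
      drop <- setdiff(seq_len(3L), qx$pivot[seq_len(qx$rank)])
      .fail("fit_rfi: rank-deficient design (collinear column: %s)",
            paste(cols[drop], collapse = ", "))
    }
    fit <- lm(total_fi ~ mbw + wg, data = d)
    b <- coef(fit)
    rss <- sum(fit$residuals^2)
    tss <- sum((d$total_fi - mean(d$total_fi))^2)
    structure(list(b0 = unname(b[1]), b1 = unname(b[2]), b2 = unname(b[3]),
                   residual_sd = sqrt(rss / max(1L, fit$df.residual)),
                   r_squared = if (tss > 0) 1 - rss / tss else 1,
                   n = nrow(d)),
              class = "rfi_fit")
  }
  if (by_sex) {
    fits <- lapply(split(records, records$sex), one_fit)
    records$rfi <- NA_real_
    for (s in names(fits)) {
      i <- records$sex == s
      f <- fits[[s]]
      records$rfi[i] <- records$total_fi[i] -
        (f$b0 + f$b1 * records$mbw[i] + f$b2 * records$wg[i])
    }
    fit <- fits
  } else {
    fit <- one_fit(records)
    records$rfi <- records$total_fi -
      (fit$b0 + fit$b1 * records$mbw + fit$b2 * records$wg)
  }
  records$fcr <- ifelse(records$adg > 0, records$dfi / records$adg, NA_real_)
  list(fit = fit, records = records)
}

#' @export
print.rfi_fit <- function(x, ...) {
  cat(sprintf(
    "RFI regression (n = %d): FI = %.3f + %.4f * BW^0.75 + %.4f * WG\n",
    x$n, x$b0, x$b1, x$b2))
  cat(sprintf("  residual SD = %.2f g, R^2 = %.3f\n", x$residual_sd,
              x$r_squared))
  invisible(x)
}

#' Select the phenotypic extremes of RFI
#'
#' The low group contains the `n_per_tail` smallest RFI values, the high
#' group the largest. Ties are broken deterministically by ascending
#' `bird_id`; a tie crossing either cut emits a warning.
#'
#' @param records data.frame with `rfi` and `bird_id` columns.
#' @param n_per_tail birds per tail (at most half the flock).
#' @return list with `low` and `high` data.frames.
#' @export
select_extremes <- function(records, n_per_tail) {
  if (n_per_tail > nrow(records) / 2)
    .fail("select_extremes: n_per_tail exceeds half the flock")
  if (anyNA(records$rfi)) .fail("select_extremes: rfi not computed")
  ord <- order(records$rfi, records$bird_id)
  low <- records[ord[seq_len(n_per_tail)], ]
  high <- records[rev(ord)[seq_len(n_per_tail)], ]
  cut_low <- records$rfi[ord[n_per_tail]]
  cut_high <- records$rfi[rev(ord)[n_per_tail]]
  if (nrow(records) > 2L * n_per_tail) {
    inner <- ord[(n_per_tail + 1):(nrow(records) - n_per_tail)]
    if (any(records$rfi[inner] == cut_low) ||
        any(records$rfi[inner] == cut_high))
      warning("select_extremes: ties at the cut resolved by bird_id")
  }
  list(low = low, high = high)
}

#' Partition an extreme group into replicate sequencing pools
#'
#' Deterministic round-robin by RFI rank (within sex when
#' `sex_balanced`), so replicate pools are matched on the phenotype
#' distribution.
#'
#' @param group data.frame of one extreme group (`bird_id`, `rfi`, `sex`).
#' @param n_pools number of replicate pools.
#' @param pool_size birds per pool; `n_pools * pool_size` must equal the
#'   group size.
#' @param sex_balanced require equal sex counts per pool.
#' @return `group` with a `pool` column (1..n_pools).
#' @export
build_pools <- function(group, n_pools, pool_size, sex_balanced = FALSE) {
  if (n_pools * pool_size != nrow(group))
    .fail("build_pools: %d birds cannot fill %d pools of %d",
          nrow(group), n_pools, pool_size)
  if (sex_balanced) {
    tab <- table(group$sex)
    if (any(tab %% n_pools != 0))
      .fail("build_pools: sex counts (%s) not divisible by %d pools",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
            n_pools)
    parts <- split(group, group$sex)
  } else {
    parts <- list(group)
  }
  out <- lapply(parts, function(d) {
    d <- d[order(d$rfi, d$bird_id), ]
    d$pool <- rep_len(seq_len(n_pools), nrow(d))
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$pool, res$rfi, res$bird_id), ]
}

#' Two-group trait summary with Student's t-tests
#'
#' Mean and SD per trait per group plus the equal-variance two-sample
#' t-test p-value, for the traits RFI, DFI, initial/final body weight,
#' ADG and FCR.
#'
#' @param low,high data.frames of the two extreme groups with derived
#'   trait columns (from [fit_rfi()]).
#' @param traits trait columns to summarize.
#' @return data.frame: trait, low_mean, low_sd, high_mean, high_sd,
#'   p_value.
#' @export
group_summary <- function(low, high,
                          traits = c("rfi", "dfi", "initial_bw", "final_bw",
                                     "adg", "fcr")) {
  if (nrow(low) == 0L || nrow(high) == 0L)
    .fail("group_summary: empty group")
  traits <- intersect(traits, intersect(names(low), names(high)))
  rows <- lapply(traits, function(tr) {
    a <- low[[tr]]; b <- high[[tr]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    p <- if (sd(c(a, b)) == 0) 1 else
      t.test(a, b, var.equal = TRUE)$p.value
    data.frame(trait = tr, low_mean = mean(a), low_sd = sd(a),
               high_mean = mean(b), high_sd = sd(b), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
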