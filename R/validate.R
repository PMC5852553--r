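#' Numerator relationship matrix by the tabular method
#'
#' `A[i,i] = 1 + A[sire,dam]/2`; `A[i,j] = (A[j,sire] + A[j,dam]) / 2` for
#' older `j`; unknown parents contribute 0. Inbreeding enters through the
#' parents' relationship; the pedigree is topologically sorted first and
#' a cycle is a fatal error naming the animals involved.
#'
#' @param pedigree data.frame with `animal`, `sire`, `dam` (NA or absent
#'   id = unknown parent).
#' @return symmetric matrix with dimnames in the input animal order.
#' @export
build_a_matrix <- function(pedigree) {
  ids <- pedigree$animal
  if (anyDuplicated(ids)) .fail("build_a_matrix: duplicated animal id")
  n <- length(ids)
  sire <- match(pedigree$sire, ids)
  dam <- match(pedigree$dam, ids)
  # Kahn topological sort (parents before offspring)
  indeg <- (!is.na(sire)) + (!is.na(dam))
  order_idx <- integer(0)
  ready <- which(indeg == 0L)
  children <- lapply(seq_len(n), function(i)
    which((!is.na(sire) & sire == i) | (!is.na(dam) & dam == i)))
  remaining <- rep(TRUE, n)
  pending <- indeg
  while (length(ready)) {
    i <- ready[1]; ready <- ready[-1]
    remaining[i] <- FALSE
    order_idx <- c(order_idx, i)
    for (ch in children[[i]]) {
      dec <- sum(c(sire[ch], dam[ch]) == i, na.rm = TRUE)
      pending[ch] <- pending[ch] - dec
      if (pending[ch] == 0L && remaining[ch]) ready <- c(ready, ch)
    }
  }
  if (any(remaining))
    .fail("build_a_matrix: pedigree cycle involving: %s",
          paste(ids[remaining], collapse = ", "))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- integer(0)
  for (i in order_idx) {
    s <- sire[i]; d <- dam[i]
    if (length(done)) {
      row_s <- if (!is.na(s)) A[s, done] else 0
      row_d <- if (!is.na(d)) A[d, done] else 0
      A[i, done] <- (row_s + row_d) / 2
      A[done, i] <- A[i, done]
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
    done <- c(done, i)
  }
  A
}

#' Solve the animal-model mixed-model equations (BLUP)
#'
#' Solves Henderson's system
#' `[X'X X'Z; Z'X Z'Z + lambda A^-1] [b; a] = [X'y; Z'y]` with
#' `lambda = sigma2_e / sigma2_a`, and verifies the solution to a
#' relative residual of 1e-8.
#'
#' @param y phenotype vector (one record per phenotyped animal).
#' @param X fixed-effect design matrix (n x p).
#' @param Z animal incidence matrix (n x q), mapping records to pedigree
#'   animals.
#' @param A numerator relationship matrix (q x q).
#' @param sigma2_a,sigma2_e variance components (both > 0).
#' @return list of class `blup_solution`: `b_hat`, `ebv` (named, length
#'   q), `lambda`, `residual` (relative MME residual), `rcond`
#'   (reciprocal condition estimate).
#' @export
solve_blup <- function(y, X, Z, A, sigma2_a, sigma2_e) {
  if (sigma2_a <= 0 || sigma2_e <= 0)
    .fail("solve_blup: variance components must be > 0")
  lambda <- sigma2_e / sigma2_a
  Ainv <- tryCatch(chol2inv(chol(A)),
                   error = function(e) .fail("solve_blup: A not positive definite: %s",
                                             conditionMessage(e)))
  XtX <- crossprod(X); XtZ <- crossprod(X, Z)
  C <- rbind(cbind(XtX, XtZ),
             cbind(t(XtZ), crossprod(Z) + lambda * Ainv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  rc <- rcond(C)
  if (rc < 1e-14)
    .fail("solve_blup: singular coefficient matrix (rcond = %.3e)", rc)
  sol <- solve(C, rhs)
  resid <- sqrt(sum((C %*% sol - rhs)^2)) / sqrt(sum(rhs^2))
  if (resid > 1e-8)
    .fail("solve_blup: relative MME residual %.2e exceeds 1e-8", resid)
  p <- ncol(X)
  structure(list(b_hat = setNames(sol[seq_len(p)], colnames(X)),
                 ebv = setNames(sol[-seq_len(p)], colnames(A)),
                 lambda = lambda, residual = resid, rcond = rc),
            class = "blup_solution")
}

#' @export
print.blup_solution <- function(x, ...) {
  cat(sprintf("animal-model BLUP: %d fixed effects, %d EBVs, lambda = %.3f\n",
              length(x$b_hat), length(x$ebv), x$lambda))
  cat(sprintf("  MME relative residual %.1e, rcond %.1e\n",
              x$residual, x$rcond))
  invisible(x)
}

#' REML variance components for the animal model
#'
#' Estimates (sigma2_a, sigma2_e) for `y = Xb + Za + e`,
#' `a ~ N(0, sigma2_a A)`. The restricted likelihood depends on the
#' marginal covariance `sigma2_a ZAZ' + sigma2_e I` only, so `ZAZ'` is
#' eigendecomposed once and the profile restricted log-likelihood is
#' maximized over the heritability `h2 = sigma2_a / (sigma2_a +
#' sigma2_e)` by one-dimensional search; the total variance is profiled
#' out in closed form. This reaches the same stationary point as EM-REML
#' iteration at a fraction of the cost. An estimate with h2 below
#' `boundary_tol` is flagged as a boundary solution.
#'
#' @param y,X,Z,A as in [solve_blup()].
#' @param boundary_tol h2 below this flags a boundary estimate (default
#'   1e-3).
#' @return list: `sigma2_a`, `sigma2_e`, `h2`, `loglik` (restricted, up
#'   to a constant), `boundary`, `convergence`.
#' @export
estimate_variance_components <- function(y, X, Z, A, boundary_tol = 1e-3) {
  n <- length(y)
  p <- qr(X)$rank
  if (n <= p + 1L) .fail("estimate_variance_components: n <= rank(X) + 1")
  if (var(y) == 0) .fail("estimate_variance_components: y has zero variance")
  G <- Z %*% A %*% t(Z)
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  restricted_ll <- function(h2) {
    v <- h2 * d + (1 - h2)
    w <- 1 / v
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(v)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - p))
  }
  opt <- optimize(restricted_ll, c(1e-6, 1 - 1e-6), maximum = TRUE,
                  tol = 1e-9)
  h2 <- opt$maximum
  v <- h2 * d + (1 - h2)
  w <- 1 / v
  beta <- solve(crossprod(Xt, Xt * w), crossprod(Xt, yt * w))
  s2 <- sum(w * (yt - Xt %*% beta)^2) / (n - p)
  list(sigma2_a = h2 * s2, sigma2_e = (1 - h2) * s2, h2 = h2,
       loglik = opt$objective, boundary = h2 < boundary_tol,
       convergence = TRUE)
}

#' Wald test of breeding values on SNP dosage
#'
#' Regresses EBV on allele dosage (0/1/2); the Wald statistic is
#' `(beta / se)^2` against chi-square with 1 df. Missing dosages are
#' dropped per SNP; monomorphic SNPs get p = 1 and a flag.
#'
#' @param ebv numeric vector of breeding values.
#' @param dosage vector or samples x SNPs matrix of dosages.
#' @return data.frame: `snp`, `n_used`, `beta`, `se`, `wald`, `p_value`,
#'   `monomorphic`.
#' @export
wald_snp_test <- function(ebv, dosage) {
  if (is.vector(dosage)) dosage <- matrix(dosage, ncol = 1)
  stopifnot(length(ebv) == nrow(dosage))
  snp <- colnames(dosage)
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(dosage)))
  out <- lapply(seq_len(ncol(dosage)), function(j) {
    g <- dosage[, j]
    ok <- !is.na(g) & !is.na(ebv)
    g <- g[ok]; e <- ebv[ok]
    n <- length(g)
    if (n < 3L || length(unique(g)) < 2L)
      return(data.frame(snp = snp[j], n_used = n, beta = NA_real_,
                        se = NA_real_, wald = NA_real_, p_value = 1,
                        monomorphic = TRUE, stringsAsFactors = FALSE))
    sxx <- sum((g - mean(g))^2)
    beta <- sum((g - mean(g)) * (e - mean(e))) / sxx
    res <- e - mean(e) - beta * (g - mean(g))
    se <- sqrt(sum(res^2) / (n - 2) / sxx)
    wald <- (beta / se)^2
    p <- max(pchisq(wald, 1, lower.tail = FALSE), 1e-300)
    data.frame(snp = snp[j], n_used = n, beta = beta, se = se, wald = wald,
               p_value = p, monomorphic = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# letter groupings for sorted class means: classes in a maximal run of
# mutually non-significant neighbours share a letter (ascending from the
# smallest mean)
lsm_letters <- function(means, pmat, alpha) {
  k <- length(means)
  ord <- order(means)
  nonsig <- pmat >= alpha
  # largest j such that sorted classes i..j are mutually non-significant
  ends <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(nonsig[ord[i:(j + 1)], ord[i:(j + 1)]]))
      j <- j + 1L
    ends[i] <- j
  }
  # keep maximal intervals only
  runs <- list()
  best_end <- 0L
  for (i in seq_len(k)) {
    if (ends[i] > best_end || best_end == 0L) {
      runs[[length(runs) + 1L]] <- ord[i:ends[i]]
      best_end <- ends[i]
    }
  }
  letters_out <- rep("", k)
  for (r in seq_along(runs))
    letters_out[runs[[r]]] <- paste0(letters_out[runs[[r]]], letters[r])
  letters_out
}

#' Genotype least-squares means and overall genotype test
#'
#' Fits the fixed-effects model `y ~ sex + genotype` (no interaction).
#' The least-squares mean of a genotype class is the model prediction
#' averaged over the sex levels; with sex-balanced classes it equals the
#' raw class mean. Pairwise class differences are tested with t
#' contrasts and summarized as letter groupings at 0.05 (lowercase) and
#' 0.01 (uppercase); the overall genotype effect is the extra-sum-of-
#' squares F test.
#'
#' @param y response (raw RFI, g).
#' @param genotype character vector of class labels (e.g. "AA").
#' @param sex factor/character of sex codes.
#' @return list of class `genotype_lsm`: `lsm` (data.frame `genotype`,
#'   `n`, `lsm`, `se`, `letters_05`, `letters_01`), `pairwise_p` (matrix),
#'   `overall_p`, `df_residual`.
#' @export
genotype_lsm <- function(y, genotype, sex) {
  ok <- !is.na(y) & !is.na(genotype) & !is.na(sex)
  y <- y[ok]; genotype <- as.character(genotype)[ok]
  sex <- as.character(sex)[ok]
  classes <- sort(unique(genotype))
  if (length(classes) < 2L) .fail("genotype_lsm: < 2 genotype classes")
  gf <- factor(genotype, levels = classes)
  sf <- factor(sex)
  X <- model.matrix(~ sf + gf)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  df_res <- length(y) - fit$rank
  s2 <- sum(fit$residuals^2) / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  n_sex <- nlevels(sf)
  contrast_for <- function(cl) {
    cv <- numeric(ncol(X))
    names(cv) <- colnames(X)
    cv["(Intercept)"] <- 1
    if (n_sex > 1)
      cv[paste0("sf", levels(sf)[-1])] <- 1 / n_sex
    if (cl != classes[1]) cv[paste0("gf", cl)] <- 1
    cv
  }
  cmat <- vapply(classes, contrast_for, numeric(ncol(X)))
  lsm <- drop(crossprod(cmat, beta))
  se <- sqrt(s2 * colSums(cmat * (XtXinv %*% cmat)))
  k <- length(classes)
  pmat <- matrix(1, k, k, dimnames = list(classes, classes))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    cd <- cmat[, a] - cmat[, b]
    sed <- sqrt(s2 * sum(cd * (XtXinv %*% cd)))
    tstat <- (lsm[a] - lsm[b]) / sed
    pmat[a, b] <- pmat[b, a] <- 2 * pt(abs(tstat), df_res, lower.tail = FALSE)
  }
  # overall genotype F: extra sum of squares over the sex-only model
  X0 <- model.matrix(~ sf)
  fit0 <- lm.fit(X0, y)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit$residuals^2)
  df_extra <- fit$rank - fit0$rank
  Fg <- ((rss0 - rss1) / df_extra) / s2
  overall_p <- pf(Fg, df_extra, df_res, lower.tail = FALSE)
  structure(list(
    lsm = data.frame(genotype = classes,
                     n = as.integer(table(gf)),
                     lsm = unname(lsm), se = unname(se),
                     letters_05 = lsm_letters(lsm, pmat, 0.05),
                     letters_01 = toupper(lsm_letters(lsm, pmat, 0.01)),
                     stringsAsFactors = FALSE),
    pairwise_p = pmat, overall_p = overall_p, df_residual = df_res),
    class = "genotype_lsm")
}

#' Additive and dominance effects from genotype least-squares means
#'
#' `a = (LSM_hom1 - LSM_hom2) / 2` (hom1 = the alphabetically first
#' homozygote class, fixing the sign) and
#' `d = LSM_het - (LSM_hom1 + LSM_hom2) / 2`. Pure arithmetic; inputs may
#' be vectors.
#'
#' @param lsm_hom1,lsm_het,lsm_hom2 least-squares means of the first
#'   homozygote, the heterozygote and the second homozygote (g).
#' @return list with `a_eff` and `d_eff` (g).
#' @examples
#' additive_dominance(35.02, 9.91, 6.20)  # a = 14.41, d = -10.70
#' @export
additive_dominance <- function(lsm_hom1, lsm_het, lsm_hom2) {
  list(a_eff = (lsm_hom1 - lsm_hom2) / 2,
       d_eff = lsm_het - (lsm_hom1 + lsm_hom2) / 2)
}

#' Validation-population association driver
#'
#' Builds the relationship matrix, obtains variance components (REML
#' unless `h2` is supplied), solves the animal model for breeding
#' values, Wald-tests every SNP against the EBVs, and decomposes the
#' genotype effect of each significant SNP into additive and dominance
#' components from the genotype least-squares means of raw RFI.
#'
#' @param dosage samples x SNPs dosage matrix (rownames = bird ids).
#' @param genotype_labels matching character matrix of genotype classes.
#' @param phenotypes data.frame with `bird_id`, `sex`, `rfi`.
#' @param pedigree pedigree data.frame covering all phenotyped birds.
#' @param h2 optional fixed heritability; when NULL, REML is run.
#' @param alpha significance cutoff for the Wald screen (raw p, default
#'   0.05; no multiplicity correction, matching the validation design).
#' @return list of class `validation_assoc`: `assoc` (per-SNP Wald
#'   table), `genotype_effects` (per significant SNP with 3 classes:
#'   LSMs, letters, overall p, `a_eff`, `d_eff`), `varcomp`, `blup`.
#' @export
validate_assoc <- function(dosage, genotype_labels, phenotypes, pedigree,
                           h2 = NULL, alpha = 0.05) {
  miss <- setdiff(phenotypes$bird_id, pedigree$animal)
  if (length(miss))
    .fail("validate_assoc: %d phenotyped bird(s) missing from pedigree",
          length(miss))
  A <- build_a_matrix(pedigree)
  y <- phenotypes$rfi
  X <- model.matrix(~ factor(sex), data = phenotypes)
  Z <- matrix(0, nrow(phenotypes), nrow(pedigree),
              dimnames = list(phenotypes$bird_id, pedigree$animal))
  Z[cbind(seq_len(nrow(phenotypes)),
          match(phenotypes$bird_id, pedigree$animal))] <- 1
  varcomp <- if (is.null(h2)) {
    estimate_variance_components(y, X, Z, A)
  } else {
    s2 <- var(y)
    list(sigma2_a = h2 * s2, sigma2_e = (1 - h2) * s2, h2 = h2,
         boundary = FALSE, convergence = NA)
  }
  blup <- solve_blup(y, X, Z, A, varcomp$sigma2_a, varcomp$sigma2_e)
  ebv <- blup$ebv[phenotypes$bird_id]
  idx <- match(phenotypes$bird_id, rownames(dosage))
  if (anyNA(idx)) .fail("validate_assoc: genotypes missing for some birds")
  dosage <- dosage[idx, , drop = FALSE]
  genotype_labels <- genotype_labels[idx, , drop = FALSE]
  assoc <- wald_snp_test(ebv, dosage)
  assoc$significant <- assoc$p_value < alpha
  sig <- which(assoc$significant)
  effects <- lapply(sig, function(j) {
    lab <- genotype_labels[, j]
    lsmfit <- genotype_lsm(phenotypes$rfi, lab, phenotypes$sex)
    tab <- lsmfit$lsm
    hom <- tab$genotype[substr(tab$genotype, 1, 1) ==
                          substr(tab$genotype, 2, 2)]
    if (length(hom) != 2L || nrow(tab) != 3L)
      return(NULL)  # a class is absent: a/d undefined
    het <- setdiff(tab$genotype, hom)
    hom <- sort(hom)
    ad <- additive_dominance(tab$lsm[tab$genotype == hom[1]],
                             tab$lsm[tab$genotype == het],
                             tab$lsm[tab$genotype == hom[2]])
    list(snp = assoc$snp[j], lsm = tab, overall_p = lsmfit$overall_p,
         a_eff = ad$a_eff, d_eff = ad$d_eff)
  })
  effects <- effects[!vapply(effects, is.null, logical(1))]
  structure(list(assoc = assoc, genotype_effects = effects,
                 varcomp = varcomp, blup = blup,
                 n_records = nrow(phenotypes)),
            class = "validation_assoc")
}
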