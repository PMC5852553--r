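test_that("A-matrix reproduces textbook relationships", {
  founders <- data.frame(animal = c("F1", "F2"), sire = NA, dam = NA,
                         sex = c("M", "F"), stringsAsFactors = FALSE)
  expect_equal(build_a_matrix(founders),
               diag(2), ignore_attr = TRUE)

  ped <- data.frame(
    animal = c("S", "D", "C1", "C2", "X"),
    sire = c(NA, NA, "S", "S", "C1"),
    dam = c(NA, NA, "D", "D", "C2"),
    sex = c("M", "F", "M", "F", "M"), stringsAsFactors = FALSE)
  A <- build_a_matrix(ped)
  expect_equal(A["S", "C1"], 0.5)       # parent-offspring
  expect_equal(A["C1", "C2"], 0.5)      # full sibs
  expect_equal(A["X", "X"], 1.25)       # offspring of full sibs
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) >= 1 & diag(A) <= 2))
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("A-matrix equals the exact recursive kinship oracle", {
  ped <- random_pedigree(10, 40, seed = 61)
  expect_equal(build_a_matrix(ped), oracle_kinship_matrix(ped),
               tolerance = 1e-8)
})

test_that("A-matrix rejects pedigree cycles, naming them", {
  bad <- data.frame(animal = c("A", "B"), sire = c("B", "A"),
                    dam = c(NA, NA), sex = c("M", "M"),
                    stringsAsFactors = FALSE)
  expect_error(build_a_matrix(bad), "cycle.*A.*B")
})

test_that("solve_blup matches a dense one-shot solve and shrinks to zero", {
  ped <- random_pedigree(8, 30, seed = 91)
  A <- build_a_matrix(ped)
  set.seed(92)
  n <- nrow(ped)
  X <- cbind(1, rbinom(n, 1, 0.5))
  colnames(X) <- c("int", "sexM")
  Z <- diag(n)
  y <- rnorm(n, 10, 3)
  sol <- solve_blup(y, X, Z, A, sigma2_a = 2, sigma2_e = 4)
  expect_lte(sol$residual, 1e-8)

  # oracle: assemble and solve the full system with base::solve
  lambda <- 4 / 2
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * solve(A)))
  want <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  expect_equal(unname(c(sol$b_hat, sol$ebv)), unname(want),
               tolerance = 1e-8)

  # infinite shrinkage: EBVs -> 0, fixed effects -> group means
  sol2 <- solve_blup(y, X, Z, A, sigma2_a = 1e-9, sigma2_e = 1)
  expect_lt(max(abs(sol2$ebv)), 1e-6)
  expect_equal(unname(sol2$b_hat[1]), mean(y[X[, 2] == 0]),
               tolerance = 1e-4)
})

test_that("BLUP EBVs track true breeding values on a simulated cohort", {
  cfg <- sim_config(seed = 14, n_validation = 800, n_val_males = 400,
                    sigma2_a = 300, sigma2_e = 700, val_n_snps = 5,
                    snp_effects = data.frame(snp = 1, a = 0, d = 0))
  v <- simulate_validation_cohort(cfg)
  A <- build_a_matrix(v$pedigree)
  X <- model.matrix(~ factor(sex), data = v$phenotypes)
  Z <- matrix(0, nrow(v$phenotypes), nrow(v$pedigree))
  Z[cbind(seq_len(nrow(v$phenotypes)),
          match(v$phenotypes$bird_id, v$pedigree$animal))] <- 1
  sol <- solve_blup(v$phenotypes$rfi, X, Z, A, 300, 700)
  truth <- v$truth$breeding_values[v$phenotypes$bird_id]
  expect_gte(cor(sol$ebv[v$phenotypes$bird_id], truth), 0.5)
})

test_that("REML guards its preconditions", {
  A <- diag(10)
  X <- matrix(1, 10, 1)
  expect_error(estimate_variance_components(rep(3, 10), X, diag(10), A),
               "zero variance")
  expect_error(estimate_variance_components(rnorm(2), matrix(1, 2, 1),
                                            diag(2), diag(2)),
               "rank")
})

test_that("REML detects a zero-heritability simulation as boundary-ish", {
  cfg <- sim_config(seed = 27, n_validation = 400, n_val_males = 200,
                    sigma2_a = 0, sigma2_e = 1000, val_n_snps = 5,
                    snp_effects = data.frame(snp = 1, a = 0, d = 0))
  v <- simulate_validation_cohort(cfg)
  A <- build_a_matrix(v$pedigree)
  X <- model.matrix(~ factor(sex), data = v$phenotypes)
  Z <- matrix(0, nrow(v$phenotypes), nrow(v$pedigree))
  Z[cbind(seq_len(nrow(v$phenotypes)),
          match(v$phenotypes$bird_id, v$pedigree$animal))] <- 1
  vc <- estimate_variance_components(v$phenotypes$rfi, X, Z, A)
  expect_lt(vc$h2, 0.15)
})

test_that("wald_snp_test equals the squared regression t statistic", {
  set.seed(71)
  for (k in 1:20) {
    n <- 50
    g <- rbinom(n, 2, 0.4)
    e <- rnorm(n) + 0.2 * g
    got <- wald_snp_test(e, g)
    fit <- summary(lm(e ~ g))$coefficients
    expect_equal(got$beta, fit["g", "Estimate"], tolerance = 1e-8)
    expect_equal(got$wald, fit["g", "t value"]^2, tolerance = 1e-8)
    expect_equal(got$p_value, pchisq(fit["g", "t value"]^2, 1,
                                     lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("wald_snp_test handles exact fits and monomorphic SNPs", {
  g <- c(0, 1, 2, 0, 1, 2)
  exact <- wald_snp_test(2 * g - 1, g)
  expect_lte(exact$p_value, 1e-300)
  mono <- wald_snp_test(rnorm(6), rep(1, 6))
  expect_true(mono$monomorphic)
  expect_equal(mono$p_value, 1)
})

test_that("genotype LSMs equal raw means when balanced and a dense oracle always", {
  set.seed(81)
  n <- 120
  geno <- sample(c("AA", "AG", "GG"), n, replace = TRUE)
  sex <- rep(c("M", "F"), n / 2)  # balanced within class by construction?
  # force exact balance within genotype class
  for (cl in unique(geno)) {
    i <- which(geno == cl)
    sex[i] <- rep(c("M", "F"), length.out = length(i))
  }
  bal <- abs(vapply(split(sex, geno), function(s) mean(s == "M"),
                    numeric(1)) - 0.5) < 1e-12
  y <- rnorm(n, 5, 2) + 3 * (geno == "AA")
  fit <- genotype_lsm(y, geno, sex)
  raw <- tapply(y, geno, mean)
  if (all(bal))
    expect_equal(fit$lsm$lsm, unname(raw[fit$lsm$genotype]),
                 tolerance = 1e-8)

  # dense normal-equations oracle on unbalanced data
  sex2 <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.7, 0.3))
  fit2 <- genotype_lsm(y, geno, sex2)
  X <- model.matrix(~ factor(sex2) + factor(geno))
  beta <- solve(crossprod(X), crossprod(X, y))
  lsm_AA <- beta[1] + 0.5 * beta[2]
  lsm_AG <- beta[1] + 0.5 * beta[2] + beta[3]
  lsm_GG <- beta[1] + 0.5 * beta[2] + beta[4]
  expect_equal(fit2$lsm$lsm, unname(c(lsm_AA, lsm_AG, lsm_GG)),
               tolerance = 1e-8)
})

test_that("noise-free planted additive effect spaces the LSMs exactly", {
  set.seed(83)
  g <- sample(0:2, 90, replace = TRUE)
  geno <- c("AA", "AG", "GG")[g + 1]
  sex <- sample(c("M", "F"), 90, replace = TRUE)
  y <- 100 + 10 * g + 5 * (sex == "M")
  fit <- genotype_lsm(y, geno, sex)
  expect_equal(diff(fit$lsm$lsm), c(10, 10), tolerance = 1e-8)
  expect_lt(fit$overall_p, 1e-12)
  # letters separate all three classes at both thresholds
  expect_equal(anyDuplicated(fit$lsm$letters_05), 0L)
})

test_that("additive_dominance reproduces published effect decompositions", {
  # verified printed values: LSMs (35.02, 9.91, 6.20) give a = 14.41,
  # d = -10.70; LSMs (6.08, 10.72, 31.98) give a = -12.95, d = -8.31
  ad1 <- additive_dominance(35.02, 9.91, 6.20)
  expect_equal(ad1$a_eff, 14.41)
  expect_equal(ad1$d_eff, -10.70)
  ad2 <- additive_dominance(6.08, 10.72, 31.98)
  expect_equal(ad2$a_eff, -12.95)
  expect_equal(ad2$d_eff, -8.31)
  # midpoint heterozygote has zero dominance for any homozygote pair
  for (k in 1:10) {
    x <- rnorm(1, 0, 20); z <- rnorm(1, 0, 20)
    expect_equal(additive_dominance(x, (x + z) / 2, z)$d_eff, 0,
                 tolerance = 1e-12)
  }
})

test_that("validate_assoc flags a planted effect SNP and decomposes it", {
  cfg <- sim_config(seed = 33, n_validation = 400, n_val_males = 200,
                    sigma2_a = 300, sigma2_e = 500, val_n_snps = 25,
                    snp_effects = data.frame(snp = 3, a = 25, d = 5))
  v <- simulate_validation_cohort(cfg)
  res <- validate_assoc(v$dosage, v$genotype_labels, v$phenotypes,
                        v$pedigree, h2 = 0.3)
  expect_true(res$assoc$significant[3])
  hit <- Filter(function(e) e$snp == colnames(v$dosage)[3],
                res$genotype_effects)
  expect_length(hit, 1L)
  # sign convention: hom1 is the alphabetically first homozygote; the
  # planted +25 g effect is on the alt allele
  expect_equal(abs(hit[[1]]$a_eff), 25, tolerance = 6)
})
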