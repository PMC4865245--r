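test_that("GRM is near 1 for duplicates and near identity for unrelated", {
  set.seed(101)
  m <- 4000
  n <- 100
  p <- runif(m, 0.1, 0.5)
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  g[2, ] <- g[1, ]
  G <- grm(tiny_geno(g))
  expect_lt(abs(G[1, 2] - 1), 0.1)
  off <- G[upper.tri(G)][-1]
  # sample-frequency centering pulls the off-diagonal mean to -1/(n-1)
  expect_lt(abs(mean(off)), 0.02)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  # centering: a sample at exactly 2p contributes nothing
  g1 <- rbind(c(1L, 1L), c(0L, 2L), c(2L, 0L))
  G1 <- grm(tiny_geno(g1), freqs = c(0.5, 0.5))
  expect_equal(unname(G1[1, ]), c(0, 0, 0))
})

test_that("PCA handles the closed-form cases with a fixed sign", {
  p_id <- pca_grm(diag(4), k = 2)
  expect_equal(p_id$var_fraction, c(0.5, 0.5))
  v <- c(3, 1, -2, 0.5)
  p_r1 <- pca_grm(tcrossprod(v), k = 2)
  expect_equal(p_r1$var_fraction[1], 1)
  expect_equal(abs(cor(p_r1$vectors[, 1], v)), 1)
  # sign convention: largest-magnitude loading positive
  expect_gt(p_r1$vectors[which.max(abs(p_r1$vectors[, 1])), 1], 0)
  expect_error(pca_grm(diag(3), k = 4), "dimension")
})

test_that("GRM eigenvectors match the SVD of the standardised genotypes", {
  sim <- simulate_structured(n_pops = 2, fst = 0.2, n_per_pop = 15,
                             n_snps = 500, seed = 33)
  ds <- run_qc(sim$dataset)$dataset
  G <- grm(ds)
  pc <- pca_grm(G, k = 3)
  p <- allele_freq(ds)
  Z <- sweep(ds$genotypes, 2, 2 * p) /
    rep(sqrt(2 * p * (1 - p)), each = n_samples(ds))
  sv <- svd(Z)
  # principal angles between the two top-3 subspaces
  angles <- acos(pmin(svd(crossprod(pc$vectors, sv$u[, 1:3]))$d, 1))
  expect_lt(max(angles), 1e-6)
})

test_that("PCA separates simulated populations linearly", {
  skip_if_not_installed("MASS")
  sim <- simulate_structured(n_pops = 3, fst = 0.12, n_per_pop = 30,
                             n_snps = 2000, seed = 35)
  pc <- pca_genotypes(run_qc(sim$dataset)$dataset, k = 3)
  scores <- pc$scores
  fit <- MASS::lda(scores[, c("PC1", "PC2")], grouping = scores$population)
  expect_equal(mean(predict(fit)$class == scores$population), 1)
})

test_that("AMOVA partitions variance sensibly at the null and the extreme", {
  # random labels on one panmictic population: among-population share ~ 0
  sim <- simulate_structured(n_pops = 1, fst = 0.1, n_per_pop = 36,
                             n_snps = 400, seed = 41)
  ds <- sim$dataset
  ds$samples$population <- rep(c("A", "B", "C"), each = 12)
  a0 <- amova(ds, n_permutations = 99, seed = 1)
  expect_lt(abs(a0$table$percentage[1]), 2)
  expect_equal(sum(a0$table$percentage[1:3]), 100, tolerance = 1e-9)

  # alternating fixed populations: FST = 1, among-population share = 100
  gfix <- rbind(matrix(0L, 6, 40), matrix(2L, 6, 40))
  dfix <- tiny_geno(gfix)
  dfix$samples$population <- rep(c("A", "B"), each = 6)
  a1 <- amova(dfix, n_permutations = 0)
  expect_equal(a1$fst, 1)
  expect_equal(a1$table$percentage[1], 100)

  # singleton population is an error
  bad <- tiny_geno(matrix(rep(0:2, length.out = 50), 5, 10))
  bad$samples$population <- c("A", "A", "A", "A", "B")
  expect_error(amova(bad, n_permutations = 0), "singleton")
})

test_that("AMOVA df mirror the allele-level decomposition", {
  sim <- simulate_structured(n_pops = 3, fst = 0.12, n_per_pop = 10,
                             n_snps = 300, seed = 43)
  a <- amova(sim$dataset, n_permutations = 0)
  N <- 30
  expect_equal(a$table$df, c(2, N - 3, N, 2 * N - 1))
})

test_that("Weir-Cockerham FST hits the null, the maximum and recovery", {
  # same frequencies everywhere: FST ~ 0
  set.seed(51)
  m <- 800
  p <- runif(m, 0.2, 0.8)
  g <- matrix(rbinom(60 * m, 2, rep(p, each = 60)), 60, m)
  ds <- tiny_geno(g)
  ds$samples$population <- rep(c("A", "B"), each = 30)
  expect_lt(abs(fst_weir_cockerham(ds)$global), 0.01)

  # fixed difference: per-SNP FST = 1
  gfix <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))
  dfix <- tiny_geno(gfix)
  dfix$samples$population <- rep(c("A", "B"), each = 10)
  expect_equal(fst_weir_cockerham(dfix)$per_snp$fst, rep(1, 5))

  # Balding-Nichols recovery, and agreement with the AMOVA estimator
  sim <- simulate_structured(n_pops = 3, fst = 0.12, n_per_pop = 30,
                             n_snps = 3000, seed = 55)
  ds2 <- run_qc(sim$dataset)$dataset
  wc <- fst_weir_cockerham(ds2)$global
  am <- amova(ds2, n_permutations = 0)$fst
  expect_lt(abs(wc - 0.12), 0.02)
  expect_lt(abs(am - 0.12), 0.02)
  expect_lt(abs(wc - am), 0.005)
})

test_that("admixture K = 1 is the closed form and the EM is monotone", {
  sim <- simulate_structured(n_pops = 1, fst = 0.1, n_per_pop = 20,
                             n_snps = 200, seed = 61)
  fit1 <- admixture_em(sim$dataset, K = 1)
  expect_equal(unname(as.matrix(fit1$Q[, "Q1"]))[, 1], rep(1, 20))
  expect_equal(unname(fit1$P[1, ]),
               unname(pmin(pmax(allele_freq(sim$dataset), 1e-6), 1 - 1e-6)))

  sim2 <- simulate_admixed(Q = rbind(matrix(rep(c(1, 0), each = 15), ncol = 2),
                                     matrix(rep(c(0, 1), each = 15), ncol = 2)),
                           fst_between = 0.3, n_snps = 300, seed = 63)
  fit2 <- admixture_em(sim2$dataset, K = 2, seed = 2, n_restarts = 2)
  expect_true(all(diff(fit2$loglik_history) > -1e-6))
})

test_that("admixture recovers cluster membership and admixed fractions", {
  Q_true <- rbind(matrix(rep(c(1, 0), each = 20), ncol = 2),
                  matrix(rep(c(0, 1), each = 20), ncol = 2),
                  matrix(0.5, 10, 2))
  sim <- simulate_admixed(Q = Q_true, fst_between = 0.3, n_snps = 800,
                          seed = 65)
  fit <- admixture_em(sim$dataset, K = 2, seed = 3, n_restarts = 3)
  Q <- as.matrix(fit$Q[, c("Q1", "Q2")])
  # align clusters to truth by the first unadmixed block
  if (mean(Q[1:20, 1]) < 0.5) Q <- Q[, 2:1]
  expect_true(all(Q[1:20, 1] > 0.95))
  expect_true(all(Q[21:40, 2] > 0.95))
  expect_lt(abs(mean(Q[41:50, 1]) - 0.5), 0.05)
  expect_true(all(abs(Q[41:50, 1] - 0.5) < 0.15))
})

test_that("admixture runs and CV are deterministic under a seed", {
  sim <- simulate_structured(n_pops = 2, fst = 0.25, n_per_pop = 10,
                             n_snps = 150, seed = 67)
  f1 <- admixture_em(sim$dataset, K = 2, seed = 9, n_restarts = 2)
  f2 <- admixture_em(sim$dataset, K = 2, seed = 9, n_restarts = 2)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$loglik, f2$loglik)

  cv1 <- admixture_cv(sim$dataset, 1:2, folds = 3, seed = 5,
                      n_restarts = 1, max_iter = 200, tol = 1e-3)
  cv2 <- admixture_cv(sim$dataset, 1:2, folds = 3, seed = 5,
                      n_restarts = 1, max_iter = 200, tol = 1e-3)
  expect_identical(cv1$cv_error, cv2$cv_error)
})

test_that("cross-validation prefers K = 1 for panmictic data", {
  sim <- simulate_structured(n_pops = 1, fst = 0.1, n_per_pop = 30,
                             n_snps = 300, seed = 69)
  cv <- admixture_cv(sim$dataset, 1:3, folds = 3, seed = 7,
                     n_restarts = 1, max_iter = 200, tol = 1e-3)
  expect_identical(attr(cv, "best_K"), 1L)
})
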