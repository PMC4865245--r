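test_that("ld_from_freqs reproduces the closed-form cases", {
  expect_equal(ld_from_freqs(0.5, 0.5, 0.25),
               tibble::tibble(D = 0, D_prime = 0, r2 = 0))
  expect_equal(ld_from_freqs(0.5, 0.5, 0.5),
               tibble::tibble(D = 0.25, D_prime = 1, r2 = 1))
  res <- ld_from_freqs(0.5, 0.5, 0.35)
  expect_equal(res$D, 0.10)
  expect_equal(res$r2, 0.16)
  expect_equal(res$D_prime, 0.4)
  expect_error(ld_from_freqs(0, 0.5, 0), "fixed locus")
})

test_that("EM equals direct haplotype counts when phase is observed", {
  # no double heterozygotes: every haplotype is phase-known
  x <- c(0L, 0L, 1L, 2L, 2L, 1L)
  y <- c(0L, 1L, 0L, 2L, 1L, 2L)
  ds <- tiny_geno(cbind(x, y))
  em <- em_haplotype_freqs(ds, 1L, 2L)
  # hand count: haplotypes per individual
  # (0,0)->aa x2; (0,1)->aa,aB; (1,0)->aa,bA... counting coded alleles:
  hap_bb <- 2 * sum(x == 2 & y == 2) + sum(x == 2 & y == 1) +
    sum(x == 1 & y == 2)
  expect_equal(em$p_ab, hap_bb / 12)
  expect_equal(em$p_a, mean(x) / 2)
  expect_equal(em$p_b, mean(y) / 2)
})

test_that("identical dosage vectors give perfect coupling even with a
           double heterozygote", {
  x <- c(0L, 1L, 2L, 1L, 0L)
  ds <- tiny_geno(cbind(x, x))
  em <- em_haplotype_freqs(ds, 1L, 2L)
  ld <- ld_from_freqs(em$p_a, em$p_b, em$p_ab)
  expect_equal(ld$r2, 1, tolerance = 1e-8)
  expect_equal(ld$D_prime, 1, tolerance = 1e-8)
})

test_that("EM matches the grid-search likelihood oracle on random tables", {
  set.seed(7)
  for (k in 1:20) {
    cnt <- random_geno_table(n = 50)
    em <- snppop:::em_hap_from_counts(matrix(cnt, 1))
    oracle <- grid_hap_oracle(cnt)
    expect_equal(unname(em[1, "p_ab"]), unname(oracle["p_ab"]),
                 tolerance = 1e-4, label = paste("table", k))
  }
})

test_that("independent loci at p = 0.5 give p_ab near 0.25", {
  set.seed(11)
  n <- 10000
  ds <- tiny_geno(cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5)))
  em <- em_haplotype_freqs(ds, 1L, 2L)
  expect_lt(abs(em$p_ab - 0.25), 0.01)
})

test_that("EM r2 recovers the haplotypic r2 of phased simulations", {
  set.seed(21)
  n <- 2000
  # sample haplotypes from a distribution with real LD, collapse to
  # genotypes, compare EM r2 with the r2 of the phased haplotypes
  hap_p <- c(0.35, 0.15, 0.05, 0.45)
  h1 <- sample(4, n, replace = TRUE, prob = hap_p)
  h2 <- sample(4, n, replace = TRUE, prob = hap_p)
  dose <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  ds <- tiny_geno(cbind(dose[h1, 1] + dose[h2, 1],
                        dose[h1, 2] + dose[h2, 2]))
  em <- em_haplotype_freqs(ds, 1L, 2L)
  em_r2 <- ld_from_freqs(em$p_a, em$p_b, em$p_ab)$r2
  hap_counts <- tabulate(c(h1, h2), 4) / (2 * n)
  pa <- hap_counts[3] + hap_counts[4]
  pb <- hap_counts[2] + hap_counts[4]
  true_r2 <- ld_from_freqs(pa, pb, hap_counts[4])$r2
  expect_lt(abs(em_r2 - true_r2), 0.02)
})

test_that("r2 never exceeds D_prime squared on computed pairs", {
  set.seed(13)
  ds13 <- tiny_geno(matrix(rbinom(30 * 60, 2, runif(60, 0.1, 0.9)[
    rep(1:60, each = 30)]), 30, 60), position_bp = 1:60 * 5000L)
  pd <- ld_pairs(ds13, max_distance_bp = 500000)
  pd <- pd[!is.na(pd$r2), ]
  expect_gt(nrow(pd), 100)
  expect_true(all(pd$r2 <= pd$D_prime^2 + 1e-12))
  expect_true(all(pd$r2 >= 0 & pd$r2 <= 1 + 1e-12))
  expect_true(all(pd$D_prime >= 0 & pd$D_prime <= 1 + 1e-12))
})

test_that("pruning collapses duplicates and respects the threshold", {
  set.seed(31)
  base <- rbinom(40, 2, 0.5)
  g <- cbind(base, base, rbinom(40, 2, 0.3), rbinom(40, 2, 0.4))
  ds <- tiny_geno(g)
  kept <- ld_prune(ds)
  expect_length(intersect(c("s1", "s2"), kept), 1L)

  sim <- simulate_structured(n_pops = 1, fst = 0.1, n_per_pop = 50,
                             n_snps = 30, seed = 17)
  all_kept <- ld_prune(sim$dataset, r2_threshold = 1)  # nothing exceeds 1
  expect_identical(all_kept, sim$dataset$map$snp_id)
})

test_that("pruning matches the brute-force greedy oracle on a toy", {
  set.seed(41)
  # 10 SNPs with blocks of correlated loci
  n <- 80
  a <- rbinom(n, 2, 0.5); b <- rbinom(n, 2, 0.4); cc <- rbinom(n, 2, 0.3)
  flip <- function(v, k) { i <- sample(n, k); v[i] <- 2 - v[i]; v }
  g <- cbind(a, flip(a, 6), flip(a, 12), b, flip(b, 4), cc,
             rbinom(n, 2, 0.45), flip(cc, 10), rbinom(n, 2, 0.35),
             flip(b, 18))
  ds <- tiny_geno(g)
  kept <- ld_prune(ds, window_snps = 50, step_snps = 5, r2_threshold = 0.2)

  pd <- ld_pairs(ds, pairs = t(utils::combn(10, 2)))
  r2m <- matrix(0, 10, 10)
  r2m[cbind(match(pd$snp_i, ds$map$snp_id),
            match(pd$snp_j, ds$map$snp_id))] <- pd$r2
  r2m <- pmax(r2m, t(r2m))
  oracle_idx <- prune_oracle(r2m, snp_maf(ds), ds$map$position_bp, 0.2)
  expect_identical(kept, ds$map$snp_id[oracle_idx])

  # pruned-set property: no retained pair above the threshold
  kept_ds <- ds[, kept]
  pd2 <- ld_pairs(kept_ds, pairs = t(utils::combn(length(kept), 2)))
  expect_true(all(pd2$r2 <= 0.2 + 1e-12, na.rm = TRUE))
})

test_that("decay binning uses half-open kb intervals", {
  pos <- c(0L, 10000L, 15000L, 25000L) + 1L
  g <- matrix(rbinom(30 * 4, 2, 0.5), 30, 4)
  ds <- tiny_geno(g, position_bp = pos)
  pd <- ld_pairs(ds)
  tab <- snppop:::bin_ld_pairs(pd)
  # distances: 10000, 15000, 25000 (from s1), 5000, 15000 (s2), 10000 (s3)
  expect_identical(tab$n_pairs[tab$interval == "0-10kb"], 1L)   # 5000
  expect_identical(tab$n_pairs[tab$interval == "10-20kb"], 4L)  # 10k x2, 15k x2
  expect_identical(tab$n_pairs[tab$interval == "20-40kb"], 1L)  # 25000
})

test_that("unlinked pairs decay to the 1/n sampling floor", {
  sim <- simulate_structured(n_pops = 1, fst = 0.1, n_per_pop = 100,
                             n_snps = 200, seed = 23)
  tab <- ld_decay_table(sim$dataset, by_population = FALSE)
  filled <- tab[tab$n_pairs > 50, ]
  expect_gt(nrow(filled), 2)
  expect_true(all(filled$mean_r2 > 0.003 & filled$mean_r2 < 0.03))
})

test_that("per-chromosome summary works over adjacent pairs", {
  set.seed(51)
  pos <- c(1L, 50001L, 120001L,            # chrom 1
           1L, 30001L,                     # chrom 2
           1L, 10001L, 20001L)             # chrom 3
  chrom <- c("1", "1", "1", "2", "2", "3", "3", "3")
  g <- matrix(rbinom(40 * 8, 2, 0.5), 40, 8)
  g[, 2] <- g[, 1]                         # duplicated adjacent pair
  ds <- tiny_geno(g, chromosome = chrom, position_bp = pos)
  tab <- per_chromosome_ld(ds)
  row1 <- tab[tab$chromosome == "1", ]
  expect_identical(row1$n_snps, 3L)
  expect_equal(row1$mean_dist_kb, 60)      # (50 + 70) / 2
  expect_equal(row1$min_dist_kb, 50)
  expect_equal(row1$max_dist_kb, 70)
  # duplicate pair contributes r2 = D' = 1 to the chrom-1 averages
  pd <- ld_pairs(ds, pairs = cbind(1L, 2L))
  expect_equal(pd$r2, 1)
  expect_equal(pd$D_prime, 1)

  single <- tiny_geno(matrix(rbinom(40, 2, 0.5), 40, 1))
  tab2 <- per_chromosome_ld(single)
  expect_identical(tab2$n_snps, 1L)
  expect_true(is.na(tab2$mean_r2))
})
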