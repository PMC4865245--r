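write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("PED/MAP parsing applies the major/minor coding rule", {
  map <- write_lines_tmp(c("1 snp1 0 1000", "1 snp2 0 2000"))
  ped <- write_lines_tmp(c(
    "F1 id1 0 0 0 -9 A A A A",
    "F1 id2 0 0 0 -9 A G G G",
    "F1 id3 0 0 0 -9 G G 0 0"
  ))
  ds <- read_ped_map(ped, map)
  # snp1: A x4, G x3 -> A major, codes = G count
  expect_identical(unname(ds$genotypes[, "snp1"]), c(0L, 1L, 2L))
  expect_identical(ds$map$allele_a[1], "A")
  expect_identical(ds$map$allele_b[1], "G")
  # snp2: A and G tie 2-2 -> lexicographic major A, codes count G;
  # missing pair -> NA
  expect_identical(unname(ds$genotypes[, "snp2"]), c(0L, 2L, NA))
  expect_identical(ds$map$allele_a[2], "A")
  expect_identical(ds$samples$population, rep("F1", 3))
})

test_that("half-missing allele pairs are treated as missing with a warning", {
  map <- write_lines_tmp("1 snp1 0 1000")
  ped <- write_lines_tmp(c("F a 0 0 0 -9 A 0", "F b 0 0 0 -9 A G"))
  expect_warning(ds <- read_ped_map(ped, map), "half-missing")
  expect_true(is.na(ds$genotypes[1, 1]))
})

test_that("parse errors name the offending line or SNP", {
  map <- write_lines_tmp(c("1 snp1 0 1000", "1 snp2 0 2000"))
  ped_short <- write_lines_tmp("F a 0 0 0 -9 A A")
  expect_error(read_ped_map(ped_short, map), "line 1")
  ped_tri <- write_lines_tmp(c("F a 0 0 0 -9 A A C C",
                               "F b 0 0 0 -9 G G C C",
                               "F c 0 0 0 -9 T T C C"))
  expect_error(read_ped_map(ped_tri, map), "snp1")
})

test_that("write/read round trip is the identity, including missing codes", {
  sim <- simulate_structured(n_pops = 2, fst = 0.2, n_per_pop = 8,
                             n_snps = 60, seed = 4)
  ds <- inject_missingness(sim$dataset, sample_rates = 0.05, seed = 2)
  ds <- canonical_coding(ds)
  ped <- withr::local_tempfile(); map <- withr::local_tempfile()
  write_ped_map(ds, ped, map)
  back <- read_ped_map(ped, map)
  expect_identical(back$genotypes, ds$genotypes)
  expect_identical(back$samples, ds$samples)
  expect_identical(back$map$snp_id, ds$map$snp_id)
  expect_identical(back$map$position_bp, ds$map$position_bp)
  # allele labels agree wherever the original observed both alleles
  seen <- !is.na(ds$map$allele_b) & snp_maf(ds) > 0
  expect_identical(back$map$allele_a[seen], ds$map$allele_a[seen])
  expect_identical(back$map$allele_b[seen], ds$map$allele_b[seen])
})

test_that("gzip round trip and empty datasets are handled", {
  sim <- simulate_structured(n_pops = 2, fst = 0.1, n_per_pop = 5,
                             n_snps = 20, seed = 9)
  ds <- canonical_coding(sim$dataset)
  ped <- paste0(withr::local_tempfile(), ".gz")
  map <- paste0(withr::local_tempfile(), ".gz")
  write_ped_map(ds, ped, map)
  expect_identical(read_ped_map(ped, map)$genotypes, ds$genotypes)

  empty <- ds[integer(0), ]
  ped2 <- withr::local_tempfile(); map2 <- withr::local_tempfile()
  write_ped_map(empty, ped2, map2)
  expect_identical(length(readLines(ped2)), 0L)
  expect_identical(length(readLines(map2)), n_snps(ds))
})

test_that("merge keeps common SNPs and flips reversed codings", {
  g1 <- tiny_geno(rbind(c(0L, 0L, 1L), c(1L, 0L, 2L), c(2L, 1L, 1L)))
  g2 <- tiny_geno(rbind(c(2L, 0L), c(1L, 1L)))
  g2$samples$sample_id <- c("j1", "j2")
  g2$samples$population <- "P2"
  g2$map <- g1$map[c(1, 3), ]       # common SNPs s1, s3
  # reverse the coding of s1 in the second dataset
  g2$map$allele_a[1] <- "G"; g2$map$allele_b[1] <- "A"
  colnames(g2$genotypes) <- g2$map$snp_id

  m <- merge_datasets(list(g1, g2))
  expect_identical(m$map$snp_id, c("s1", "s3"))
  expect_identical(n_samples(m), 5L)
  # s1 codes of dataset 2 flipped: 2 -> 0, 1 -> 1
  expect_identical(unname(m$genotypes[4:5, "s1"]), c(0L, 1L))
  # s3 unchanged
  expect_identical(unname(m$genotypes[4:5, "s3"]), c(0L, 1L))
  # heterozygote count preserved under the flip
  expect_identical(sum(m$genotypes[4:5, "s1"] == 1L),
                   sum(g2$genotypes[, "s1"] == 1L))
})

test_that("merge rejects incompatible alleles and non-disjoint samples", {
  g1 <- tiny_geno(rbind(c(0L, 1L), c(1L, 2L)))
  g2 <- tiny_geno(rbind(c(0L, 1L), c(1L, 2L)))
  g2$samples$sample_id <- c("j1", "j2")
  g2$map$allele_a[1] <- "C"; g2$map$allele_b[1] <- "T"
  expect_error(merge_datasets(list(g1, g2)), "s1")
  g3 <- tiny_geno(rbind(c(0L, 1L), c(1L, 2L)))   # same ids as g1
  expect_error(merge_datasets(list(g1, g3)), "disjoint")
})

test_that("merge of identically coded datasets is plain concatenation and
           is associative under first-dataset anchoring", {
  sim <- simulate_structured(n_pops = 3, fst = 0.15, n_per_pop = 6,
                             n_snps = 40, seed = 12)
  parts <- split_populations(sim$dataset)
  m12_3 <- merge_datasets(list(merge_datasets(parts[1:2]), parts[[3]]))
  m123 <- merge_datasets(parts)
  expect_identical(m123$genotypes, m12_3$genotypes)
  expect_identical(m123$genotypes,
                   sim$dataset$genotypes[, m123$map$snp_id])
})

test_that("subset_autosomes keeps chromosomes 1-29 only", {
  g <- tiny_geno(matrix(0:2, 3, 4), chromosome = c("1", "29", "X", "30"))
  expect_identical(subset_autosomes(g)$map$chromosome, c("1", "29"))
  all_auto <- tiny_geno(matrix(0:2, 3, 2), chromosome = c("2", "3"))
  expect_identical(subset_autosomes(all_auto)$map, all_auto$map)
  expect_identical(n_snps(subset_autosomes(g[, "s3"])), 0L)
})
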