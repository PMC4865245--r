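#' QC threshold configuration
#'
#' Defaults follow the standard chip-QC cascade: samples with call rate
#' below 95% are removed first, then SNPs failing marker call rate (<95%),
#' minor allele frequency (<0.05) and the exact Hardy-Weinberg test
#' (p < 0.001), in that order.
#'
#' @param sample_call_threshold,snp_call_threshold,maf_threshold Fractions
#'   in `[0, 1]`.
#' @param hwe_p_threshold Probability in `[0, 1]`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(sample_call_threshold = 0.95,
                      snp_call_threshold = 0.95,
                      maf_threshold = 0.05,
                      hwe_p_threshold = 0.001) {
  thr <- c(sample_call_threshold, snp_call_threshold, maf_threshold,
           hwe_p_threshold)
  stopifnot(all(thr >= 0), all(thr <= 1))
  structure(
    list(sample_call_threshold = sample_call_threshold,
         snp_call_threshold = snp_call_threshold,
         maf_threshold = maf_threshold,
         hwe_p_threshold = hwe_p_threshold),
    class = "qc_config"
  )
}

#' Per-sample call rates
#'
#' @param x A [geno_data] object with at least one SNP.
#' @return Tibble with `sample_id`, `population`, `call_rate` (fraction of
#'   non-missing genotypes).
#' @export
sample_call_rates <- function(x) {
  stopifnot(n_snps(x) >= 1L)
  tibble::tibble(
    sample_id = x$samples$sample_id,
    population = x$samples$population,
    call_rate = unname(rowMeans(!is.na(x$genotypes)))
  )
}

#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact conditional test: given the allele counts implied by the
#' genotype table, the p-value is the summed probability of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count. Monomorphic tables return 1 by convention. All arguments are
#' vectorised.
#'
#' @param n_AA,n_AB,n_BB Genotype counts (non-negative, summing to >= 1).
#' @return P-values in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25)  # modal heterozygote count: p = 1
#' hwe_exact_p(50, 0, 50)   # extreme heterozygote deficit: p << 0.001
hwe_exact_p <- function(n_AA, n_AB, n_BB) {
  mapply(hwe_exact_p1, n_AA, n_AB, n_BB, USE.NAMES = FALSE)
}

hwe_exact_p1 <- function(n_AA, n_AB, n_BB) {
  stopifnot(n_AA >= 0, n_AB >= 0, n_BB >= 0)
  n <- n_AA + n_AB + n_BB
  stopifnot(n >= 1)
  n_r <- min(2 * n_AA + n_AB, 2 * n_BB + n_AB)   # rarer-allele copies
  if (n_r == 0) return(1)
  probs <- hwe_het_distribution(n, n_r)
  obs <- probs[names(probs) == as.character(n_AB)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Conditional distribution of the heterozygote count given n diploids and
# n_r copies of the rarer allele: P(h) proportional to
# n! / (n_hom_r! h! n_hom_c!) * 2^h, computed in log space.
hwe_het_distribution <- function(n, n_r) {
  h <- seq.int(n_r %% 2, n_r, by = 2)
  hom_r <- (n_r - h) / 2
  hom_c <- n - h - hom_r
  logw <- lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) -
    lgamma(hom_c + 1) + h * log(2)
  w <- exp(logw - max(logw))
  stats::setNames(w / sum(w), h)
}

# Per-SNP QC statistics on the current matrix: call rate, MAF, HWE p.
snp_qc_stats <- function(x) {
  g <- x$genotypes
  n_AA <- colSums(g == 0L, na.rm = TRUE)
  n_AB <- colSums(g == 1L, na.rm = TRUE)
  n_BB <- colSums(g == 2L, na.rm = TRUE)
  nonmiss <- n_AA + n_AB + n_BB
  p <- (n_AB + 2 * n_BB) / (2 * nonmiss)
  hwe <- rep(1, n_snps(x))
  poly <- nonmiss > 0 & p > 0 & p < 1
  hwe[poly] <- hwe_exact_p(n_AA[poly], n_AB[poly], n_BB[poly])
  tibble::tibble(
    snp_id = x$map$snp_id,
    call_rate = nonmiss / n_samples(x),
    maf = ifelse(nonmiss > 0, pmin(p, 1 - p), 0),
    hwe_p = hwe
  )
}

#' Run the QC cascade
#'
#' Applies, in order: (1) removal of samples with call rate below the
#' sample threshold; then on the surviving matrix (2) SNP call rate,
#' (3) MAF (strictly below the threshold fails; a MAF exactly at the
#' threshold is kept), (4) exact HWE. Each SNP is attributed to the first
#' criterion it fails, so the per-criterion counts are disjoint and sum
#' with the survivors to the panel size.
#'
#' @param x A [geno_data] object.
#' @param config A [qc_config()].
#' @return List with `dataset` (the filtered [geno_data]) and `report`, a
#'   one-row tibble: `n_samples_in`, `n_samples_removed`, `n_snps_in`,
#'   `n_snps_failed_call`, `n_snps_failed_maf`, `n_polymorphic`,
#'   `pct_polymorphic`, `n_snps_failed_hwe`, `n_snps_remaining`,
#'   `pct_remaining` (percentages against the pre-QC panel).
#' @export
run_qc <- function(x, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  panel <- n_snps(x)
  n_in <- n_samples(x)

  cr <- sample_call_rates(x)$call_rate
  keep_s <- cr >= config$sample_call_threshold
  x2 <- x[keep_s, ]
  if (n_samples(x2) == 0L) {
    stop("QC removed every sample; nothing left to analyse", call. = FALSE)
  }

  st <- snp_qc_stats(x2)
  fail_call <- st$call_rate < config$snp_call_threshold
  fail_maf <- !fail_call & st$maf < config$maf_threshold
  fail_hwe <- !fail_call & !fail_maf & st$hwe_p < config$hwe_p_threshold
  keep <- !(fail_call | fail_maf | fail_hwe)

  out <- x2[, keep]
  if (n_snps(out) == 0L) {
    stop("QC removed every SNP; nothing left to analyse", call. = FALSE)
  }

  report <- tibble::tibble(
    n_samples_in = n_in,
    n_samples_removed = sum(!keep_s),
    n_snps_in = panel,
    n_snps_failed_call = sum(fail_call),
    n_snps_failed_maf = sum(fail_maf),
    n_polymorphic = sum(!fail_call & st$maf > 0),
    pct_polymorphic = 100 * sum(!fail_call & st$maf > 0) / panel,
    n_snps_failed_hwe = sum(fail_hwe),
    n_snps_remaining = sum(keep),
    pct_remaining = 100 * sum(keep) / panel
  )
  list(dataset = out, report = report)
}
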