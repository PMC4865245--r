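#' Per-SNP observed and expected heterozygosity
#'
#' For each SNP, `Ho` is the heterozygote fraction among non-missing
#' genotypes and `He = 2p(1 - p)` the Hardy-Weinberg expectation at the
#' sample allele frequency `p` (plug-in estimator; set
#' `unbiased = TRUE` for the small-sample `2n/(2n - 1)` correction).
#'
#' @param x A [geno_data] object with >= 2 samples.
#' @param unbiased Apply the `2n/(2n - 1)` correction to He.
#' @return Tibble: `snp_id`, `n`, `p`, `maf`, `Ho`, `He`.
#' @export
het_stats <- function(x, unbiased = FALSE) {
  stopifnot(n_samples(x) >= 2L)
  g <- x$genotypes
  n <- unname(colSums(!is.na(g)))
  p <- unname(colMeans(g, na.rm = TRUE)) / 2
  he <- 2 * p * (1 - p)
  if (unbiased) he <- he * ifelse(n > 0, 2 * n / (2 * n - 1), NA_real_)
  tibble::tibble(
    snp_id = x$map$snp_id,
    n = n,
    p = p,
    maf = pmin(p, 1 - p),
    Ho = unname(colMeans(g == 1L, na.rm = TRUE)),
    He = he
  )
}

#' Per-individual inbreeding coefficient
#'
#' Method-of-moments excess homozygosity:
#' `f = (O_hom - E_hom) / (L - E_hom)`, where `O_hom` is the observed
#' homozygote count over the individual's non-missing SNPs, `E_hom` the
#' Hardy-Weinberg expectation `sum(1 - 2 p_k (1 - p_k))` over the same
#' SNPs, and `L` the number of non-missing SNPs. Allele frequencies are
#' estimated from `x` itself (or supplied), so per-population frequencies
#' are obtained by passing a per-population subset.
#'
#' @param x A [geno_data] object.
#' @param freqs Optional per-SNP coded-allele frequencies (defaults to the
#'   dataset's own).
#' @return Tibble: `sample_id`, `population`, `n_snps`, `o_hom`, `e_hom`,
#'   `f`. `f` is `NA` with a warning where `L = E_hom` (all SNPs fixed).
#' @export
individual_inbreeding <- function(x, freqs = NULL) {
  g <- x$genotypes
  if (is.null(freqs)) freqs <- allele_freq(x)
  stopifnot(length(freqs) == n_snps(x))
  nonmiss <- !is.na(g)
  L <- unname(rowSums(nonmiss))
  o_hom <- unname(rowSums(g != 1L, na.rm = TRUE))
  exp_hom_k <- 1 - 2 * freqs * (1 - freqs)
  e_hom <- as.vector(nonmiss %*% ifelse(is.na(exp_hom_k), 0, exp_hom_k))
  denom <- L - e_hom
  f <- ifelse(abs(denom) > 1e-12, (o_hom - e_hom) / denom, NA_real_)
  if (anyNA(f)) {
    warning("inbreeding undefined for individuals with all SNPs fixed",
            call. = FALSE)
  }
  tibble::tibble(
    sample_id = x$samples$sample_id,
    population = x$samples$population,
    n_snps = L,
    o_hom = o_hom,
    e_hom = e_hom,
    f = f
  )
}

#' Pairwise method-of-moments IBD (PI_HAT)
#'
#' Estimates the IBD-state probabilities `P(IBD = 0/1/2)` for sample pairs
#' from identity-by-state counts, by inverting the expected IBS
#' distribution given allele frequencies (the classic PLINK-style
#' method-of-moments). Negative solutions are truncated to `[0, 1]` and
#' the triple renormalised — the standard repair, which biases `pi_hat`
#' slightly upward near 0. `pi_hat = P(IBD=1)/2 + P(IBD=2)`.
#'
#' @param x A [geno_data] object (post-QC, LD-pruned data recommended).
#' @param pairs Optional two-column matrix/data frame of sample ids or row
#'   indices; default is all pairs.
#' @param freqs Optional per-SNP coded-allele frequencies; default is
#'   estimated from `x`. Pass the truth for simulation studies.
#' @param min_snps Pairs with fewer overlapping non-missing SNPs are
#'   flagged `low_confidence`.
#' @return Tibble: `id1`, `id2`, `n_snps`, `Z0`, `Z1`, `Z2`, `pi_hat`,
#'   `low_confidence`.
#' @export
pairwise_pihat <- function(x, pairs = NULL, freqs = NULL, min_snps = 100L) {
  g <- x$genotypes
  n <- n_samples(x)
  if (is.null(freqs)) freqs <- allele_freq(x)
  stopifnot(length(freqs) == n_snps(x))

  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2L))
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) {
      pairs <- cbind(match(pairs[, 1L], x$samples$sample_id),
                     match(pairs[, 2L], x$samples$sample_id))
    }
    storage.mode(pairs) <- "integer"
  }

  p <- freqs; q <- 1 - p
  usable <- !is.na(p) & p > 0 & p < 1
  # per-SNP expected IBS-state probabilities under each IBD state
  e_ibs0_z0 <- ifelse(usable, 2 * p^2 * q^2, 0)
  e_ibs1_z0 <- ifelse(usable, 4 * p^3 * q + 4 * p * q^3, 0)
  e_ibs1_z1 <- ifelse(usable, 2 * p^2 * q + 2 * p * q^2, 0)
  e_ibs2_z0 <- ifelse(usable, p^4 + q^4 + 4 * p^2 * q^2, 0)
  e_ibs2_z1 <- ifelse(usable, p^3 + q^3 + p^2 * q + p * q^2, 0)

  P <- nrow(pairs)
  out <- matrix(NA_real_, P, 5L)
  for (k in seq_len(P)) {
    xi <- g[pairs[k, 1L], ]; xj <- g[pairs[k, 2L], ]
    ok <- !is.na(xi) & !is.na(xj) & usable
    L <- sum(ok)
    if (L == 0L) { out[k, 1L] <- 0; next }
    d <- abs(xi[ok] - xj[ok])
    ibs0 <- sum(d == 2L); ibs1 <- sum(d == 1L); ibs2 <- sum(d == 0L)
    E00 <- sum(e_ibs0_z0[ok]); E10 <- sum(e_ibs1_z0[ok])
    E11 <- sum(e_ibs1_z1[ok]); E20 <- sum(e_ibs2_z0[ok])
    E21 <- sum(e_ibs2_z1[ok]); E22 <- L
    z0 <- if (E00 > 0) ibs0 / E00 else 0
    z1 <- if (E11 > 0) (ibs1 - z0 * E10) / E11 else 0
    z2 <- (ibs2 - z0 * E20 - z1 * E21) / E22
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    if (sum(z) == 0) z <- c(1, 0, 0)
    z <- z / sum(z)
    out[k, ] <- c(L, z, z[2L] / 2 + z[3L])
  }
  tibble::tibble(
    id1 = x$samples$sample_id[pairs[, 1L]],
    id2 = x$samples$sample_id[pairs[, 2L]],
    n_snps = as.integer(out[, 1L]),
    Z0 = out[, 2L], Z1 = out[, 3L], Z2 = out[, 4L],
    pi_hat = out[, 5L],
    low_confidence = out[, 1L] < min_snps
  )
}

#' Per-population diversity summary
#'
#' The Table-2-style summary: average MAF, mean expected and observed
#' heterozygosity and mean individual inbreeding per population (and for
#' the whole dataset under `"Merged"` when several populations are
#' present), computed with within-population allele frequencies. When
#' `pruned_ids` is given the same statistics are also reported on that
#' SNP subset (the LD-pruned panel).
#'
#' @param x A post-QC [geno_data] object.
#' @param pruned_ids Optional character vector of retained SNP ids.
#' @return Tibble: `population`, `panel` (`"post-QC"` / `"LD-pruned"`),
#'   `n_samples`, `n_snps`, `avg_maf`, `mean_He`, `mean_Ho`, `mean_f`.
#' @export
diversity_summary <- function(x, pruned_ids = NULL) {
  groups <- list()
  if (length(unique(x$samples$population)) > 1L) {
    groups <- split_populations(x)
    groups$Merged <- x
  } else {
    groups <- stats::setNames(list(x), unique(x$samples$population))
  }
  panels <- list(`post-QC` = NULL, `LD-pruned` = pruned_ids)
  if (is.null(pruned_ids)) panels <- panels[1L]

  purrr::imap(groups, function(g, pop) {
    purrr::imap(panels, function(ids, panel_name) {
      gg <- if (is.null(ids)) g else g[, ids]
      hs <- het_stats(gg)
      f <- individual_inbreeding(gg)
      tibble::tibble(
        population = pop, panel = panel_name,
        n_samples = n_samples(gg), n_snps = n_snps(gg),
        avg_maf = mean(hs$maf, na.rm = TRUE),
        mean_He = mean(hs$He, na.rm = TRUE),
        mean_Ho = mean(hs$Ho, na.rm = TRUE),
        mean_f = mean(f$f, na.rm = TRUE)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
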