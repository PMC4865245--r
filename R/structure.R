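#' Genomic relationship matrix
#'
#' Allele-frequency-standardised cross-products:
#' `G_ij = (1/m_ij) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))`,
#' with missing genotypes contributing 0 and the per-pair SNP count `m_ij`
#' adjusted accordingly. SNPs fixed in the dataset (`p` 0 or 1) are
#' excluded with a warning.
#'
#' @param x A post-QC, LD-pruned autosomal [geno_data] object.
#' @param freqs Optional per-SNP coded-allele frequencies.
#' @return Symmetric samples x samples matrix with sample-id dimnames.
#' @export
grm <- function(x, freqs = NULL) {
  g <- x$genotypes
  if (is.null(freqs)) freqs <- allele_freq(x)
  usable <- !is.na(freqs) & freqs > 0 & freqs < 1
  if (!all(usable)) {
    warning(sprintf("%d fixed SNPs excluded from the GRM", sum(!usable)),
            call. = FALSE)
  }
  g <- g[, usable, drop = FALSE]
  p <- freqs[usable]
  Z <- sweep(g, 2L, 2 * p, `-`) / rep(sqrt(2 * p * (1 - p)),
                                      each = nrow(g))
  miss <- is.na(Z)
  Z[miss] <- 0
  M <- tcrossprod(1 - miss)      # per-pair non-missing SNP count
  G <- tcrossprod(Z) / pmax(M, 1)
  dimnames(G) <- list(x$samples$sample_id, x$samples$sample_id)
  G
}

#' PCA of a relationship matrix
#'
#' Top-k eigenpairs of a symmetric (relationship) matrix. Variance
#' fractions are reported over the retained components (they sum to 1
#' across the k components kept). Deterministic sign convention: each
#' eigenvector's largest-magnitude loading is positive.
#'
#' @param G Symmetric matrix (e.g. from [grm()]).
#' @param k Number of components to retain.
#' @param samples Optional sample tibble (`sample_id`, `population`)
#'   carried into the scores for plotting.
#' @return Object of class `snppop_pca`: list with `values` (all
#'   eigenvalues, descending), `vectors` (n x k), `var_fraction` (length
#'   k), `scores` tibble.
#' @export
pca_grm <- function(G, k = 3L, samples = NULL) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  if (k > nrow(G)) stop("k exceeds the matrix dimension", call. = FALSE)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  top <- e$values[seq_len(k)]
  scores <- tibble::as_tibble(stats::setNames(
    as.data.frame(V), paste0("PC", seq_len(k))))
  if (!is.null(samples)) {
    scores <- dplyr::bind_cols(tibble::as_tibble(samples), scores)
  } else if (!is.null(rownames(G))) {
    scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(G)),
                               scores)
  }
  structure(
    list(values = e$values, vectors = V, var_fraction = top / sum(top),
         k = k, scores = scores),
    class = "snppop_pca"
  )
}

#' GRM-based PCA of a genotype dataset
#'
#' Convenience wrapper: [grm()] then [pca_grm()], carrying population
#' labels into the scores.
#'
#' @inheritParams grm
#' @inheritParams pca_grm
#' @return A `snppop_pca` object.
#' @export
pca_genotypes <- function(x, k = 3L, freqs = NULL) {
  pca_grm(grm(x, freqs = freqs), k = k, samples = x$samples)
}

#' @export
print.snppop_pca <- function(x, ...) {
  cat(sprintf("<snppop_pca> %d components; variance fractions: %s\n",
              x$k, paste(sprintf("%.1f%%", 100 * x$var_fraction),
                         collapse = ", ")))
  invisible(x)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Three-level allele-based AMOVA on biallelic dosages: total variance is
#' partitioned into among-population, among-individual-within-population
#' and within-individual (between an individual's two allele copies)
#' components, summed over loci. `FST` is the among-population fraction of
#' the total. Significance comes from permuting individuals among
#' populations and recomputing the among-population component, with the
#' `(b + 1)/(m + 1)` p-value estimator. Negative component estimates are
#' retained, as variance-component estimators allow.
#'
#' Missing dosages are imputed with their locus's population mean before
#' the sums of squares are formed.
#'
#' @param x A [geno_data] object with >= 2 populations of >= 2 individuals.
#' @param n_permutations Label permutations for the null (0 skips the
#'   test).
#' @param seed Integer seed for the permutations.
#' @return Object of class `snppop_amova`: `table` (source, df, SS,
#'   variance component, percentage), `fst`, `p_value`, `n_permutations`.
#' @export
amova <- function(x, n_permutations = 1000L, seed = 1L) {
  pop <- x$samples$population
  counts <- table(pop)
  if (length(counts) < 2L) {
    stop("AMOVA needs >= 2 populations", call. = FALSE)
  }
  if (any(counts < 2L)) {
    stop("AMOVA needs >= 2 individuals per population (singleton found)",
         call. = FALSE)
  }
  g <- x$genotypes
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    for (p in names(counts)) {
      rows <- pop == p
      sub <- g[rows, , drop = FALSE]
      mu <- colMeans(sub, na.rm = TRUE)
      mu[is.nan(mu)] <- 0
      idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(idx)) sub[idx] <- mu[idx[, 2L]]
      g[rows, ] <- sub
    }
  }
  N <- nrow(g)
  r <- length(counts)

  # within-individual SS: an individual's two allele copies deviate from
  # their mean only at heterozygotes, each contributing
  # (0 - 1/2)^2 + (1 - 1/2)^2 = 1/2. Imputed fractional dosages are
  # treated as homozygous-like (no within-individual spread).
  ss_wi <- 0.5 * sum(g == 1)

  ind_mean <- g / 2
  grand <- colMeans(ind_mean)
  ss_between_ind <- 2 * sum(sweep(ind_mean, 2L, grand)^2)

  ss_ap <- amova_ss_among(ind_mean, pop, counts, grand)
  ss_ai <- ss_between_ind - ss_ap

  df_a <- r - 1
  df_b <- N - r
  df_w <- N
  n_c <- (N - sum(counts^2) / N) / (r - 1)

  ms_w <- ss_wi / df_w
  ms_b <- ss_ai / df_b
  ms_a <- ss_ap / df_a
  sig_w <- ms_w
  sig_b <- (ms_b - sig_w) / 2
  sig_a <- (ms_a - sig_w - 2 * sig_b) / (2 * n_c)
  total <- sig_a + sig_b + sig_w
  fst <- sig_a / total

  p_value <- NA_real_
  if (n_permutations > 0L) {
    hits <- 0L
    withr::with_seed(seed, {
      for (b in seq_len(n_permutations)) {
        pp <- sample(pop)
        ss_ap_b <- amova_ss_among(ind_mean, pp, counts, grand)
        ss_ai_b <- ss_between_ind - ss_ap_b
        sig_b_b <- (ss_ai_b / df_b - sig_w) / 2
        sig_a_b <- (ss_ap_b / df_a - sig_w - 2 * sig_b_b) / (2 * n_c)
        if (sig_a_b >= sig_a) hits <- hits + 1L
      }
    })
    p_value <- (hits + 1) / (n_permutations + 1)
  }

  structure(
    list(
      table = tibble::tibble(
        source = c("Among populations",
                   "Among individuals within populations",
                   "Within individuals", "Total"),
        df = c(df_a, df_b, df_w, df_a + df_b + df_w),
        sum_sq = c(ss_ap, ss_ai, ss_wi, ss_ap + ss_ai + ss_wi),
        variance = c(sig_a, sig_b, sig_w, total),
        percentage = 100 * c(sig_a, sig_b, sig_w, total) / total
      ),
      fst = fst,
      p_value = p_value,
      n_permutations = as.integer(n_permutations)
    ),
    class = "snppop_amova"
  )
}

amova_ss_among <- function(ind_mean, pop, counts, grand) {
  pops <- names(counts)
  ss <- 0
  for (p in pops) {
    rows <- pop == p
    mu <- colMeans(ind_mean[rows, , drop = FALSE])
    ss <- ss + 2 * sum(rows) * sum((mu - grand)^2)
  }
  ss
}

#' @export
print.snppop_amova <- function(x, ...) {
  cat("<snppop_amova>\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("FST = %.4f; permutation p = %s (%d permutations)\n",
              x$fst,
              ifelse(is.na(x$p_value), "NA", format(x$p_value)),
              x$n_permutations))
  invisible(x)
}

#' Weir-Cockerham FST
#'
#' Per-SNP and global fixation index via the Weir-Cockerham (1984)
#' variance-components estimator for haploid-pair (genotype) data with
#' unequal sample sizes. The global value is the ratio of summed
#' among-population components to summed totals; SNPs monomorphic across
#' all populations are skipped.
#'
#' @param x A [geno_data] object with >= 2 populations.
#' @return List with `per_snp` (tibble: `snp_id`, `a`, `b`, `c`, `fst`)
#'   and `global` (scalar).
#' @export
fst_weir_cockerham <- function(x) {
  pop <- x$samples$population
  pops <- unique(pop)
  r <- length(pops)
  if (r < 2L) stop("FST needs >= 2 populations", call. = FALSE)
  g <- x$genotypes

  n_i <- sapply(pops, function(p) colSums(!is.na(g[pop == p, , drop = FALSE])))
  p_i <- sapply(pops, function(p) colMeans(g[pop == p, , drop = FALSE],
                                           na.rm = TRUE) / 2)
  h_i <- sapply(pops, function(p) colMeans(g[pop == p, , drop = FALSE] == 1L,
                                           na.rm = TRUE))
  n_i <- matrix(n_i, ncol = r); p_i <- matrix(p_i, ncol = r)
  h_i <- matrix(h_i, ncol = r)
  h_i[is.nan(h_i)] <- 0; p_i[is.nan(p_i)] <- 0

  n_tot <- rowSums(n_i)
  nbar <- n_tot / r
  n_c <- (n_tot - rowSums(n_i^2) / n_tot) / (r - 1)
  pbar <- rowSums(n_i * p_i) / n_tot
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / n_tot

  a <- (nbar / n_c) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  poly <- pbar > 0 & pbar < 1 & n_tot > 0 & nbar > 1
  per_snp <- tibble::tibble(
    snp_id = x$map$snp_id,
    a = ifelse(poly, a, NA_real_),
    b = ifelse(poly, b, NA_real_),
    c = ifelse(poly, cc, NA_real_),
    fst = ifelse(poly & (a + b + cc) != 0, a / (a + b + cc), NA_real_)
  )
  global <- sum(per_snp$a, na.rm = TRUE) /
    sum(per_snp$a + per_snp$b + per_snp$c, na.rm = TRUE)
  list(per_snp = per_snp, global = global)
}
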