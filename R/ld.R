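# Two-locus LD machinery: genotype-pair counts, vectorised EM haplotype
# frequency estimation, D / D' / r2, windowed pruning and the distance
# summaries.

# 3x3 genotype-combination counts for a set of SNP pairs.
# g: samples x SNPs dosage matrix; ii, jj: column indices per pair.
# Returns a P x 9 matrix, column 3*a + b + 1 = #(x_i = a, x_j = b),
# over samples non-missing at both loci.
pair_geno_counts <- function(g, ii, jj) {
  cols <- sort(unique(c(ii, jj)))
  sub <- g[, cols, drop = FALSE]
  i2 <- match(ii, cols)
  j2 <- match(jj, cols)
  ind <- lapply(0:2, function(v) {
    M <- sub == v
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  out <- matrix(0, length(ii), 9L)
  for (a in 0:2) {
    for (b in 0:2) {
      out[, 3L * a + b + 1L] <-
        colSums(ind[[a + 1L]][, i2, drop = FALSE] *
                  ind[[b + 1L]][, j2, drop = FALSE])
    }
  }
  out
}

# Vectorised EM over genotype-pair count tables. Only double heterozygotes
# are phase-ambiguous; the E-step splits them between the cis and trans
# configurations. Initialisation at linkage equilibrium. Returns a matrix
# with haplotype frequencies for the coded (b) alleles, margins and n.
em_hap_from_counts <- function(cnt, tol = 1e-10, max_iter = 1000L) {
  n <- rowSums(cnt)
  nh <- 2 * n
  n00 <- cnt[, 1]; n01 <- cnt[, 2]; n02 <- cnt[, 3]
  n10 <- cnt[, 4]; n11 <- cnt[, 5]; n12 <- cnt[, 6]
  n20 <- cnt[, 7]; n21 <- cnt[, 8]; n22 <- cnt[, 9]

  # phase-known haplotype counts (A = non-coded, B = coded allele)
  cAA <- 2 * n00 + n01 + n10
  cAB <- 2 * n02 + n01 + n12
  cBA <- 2 * n20 + n10 + n21
  cBB <- 2 * n22 + n12 + n21

  p1 <- (n10 + n11 + n12 + 2 * (n20 + n21 + n22)) / nh  # coded freq, locus 1
  p2 <- (n01 + n11 + n21 + 2 * (n02 + n12 + n22)) / nh  # coded freq, locus 2

  pAA <- (1 - p1) * (1 - p2)
  pAB <- (1 - p1) * p2
  pBA <- p1 * (1 - p2)
  pBB <- p1 * p2

  active <- which(n11 > 0 & nh > 0)   # everything else is already exact
  if (length(active) == 0L || all(nh == 0)) {
    idx <- integer(0)
  }
  iter <- 0L
  idx <- active
  while (length(idx) && iter < max_iter) {
    iter <- iter + 1L
    den <- pAA[idx] * pBB[idx] + pAB[idx] * pBA[idx]
    pcis <- ifelse(den > 0, pAA[idx] * pBB[idx] / den, 0.5)
    nAA <- (cAA[idx] + n11[idx] * pcis) / nh[idx]
    nBB <- (cBB[idx] + n11[idx] * pcis) / nh[idx]
    nAB <- (cAB[idx] + n11[idx] * (1 - pcis)) / nh[idx]
    nBA <- (cBA[idx] + n11[idx] * (1 - pcis)) / nh[idx]
    delta <- pmax(abs(nAA - pAA[idx]), abs(nBB - pBB[idx]),
                  abs(nAB - pAB[idx]), abs(nBA - pBA[idx]))
    pAA[idx] <- nAA; pBB[idx] <- nBB; pAB[idx] <- nAB; pBA[idx] <- nBA
    idx <- idx[delta >= tol]
  }
  # phase-known rows get their exact count-based frequencies
  exact <- setdiff(seq_along(n), active)
  if (length(exact)) {
    ok <- exact[nh[exact] > 0]
    pAA[ok] <- cAA[ok] / nh[ok]; pAB[ok] <- cAB[ok] / nh[ok]
    pBA[ok] <- cBA[ok] / nh[ok]; pBB[ok] <- cBB[ok] / nh[ok]
  }
  cbind(p_ab = pBB, p_aB = pBA, p_Ab = pAB, p_AB = pAA,
        p_a = p1, p_b = p2, n = n)
}

#' EM haplotype frequencies for one SNP pair
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased diploid
#' genotypes under random pairing of haplotypes. Only double heterozygotes
#' are phase-ambiguous; the EM splits them between the cis and trans
#' configurations each E-step, iterating until the largest frequency change
#' is below `tol` (or 1000 iterations). Samples missing either genotype are
#' dropped (pairwise-complete).
#'
#' Naming convention: `a` and `b` are the coded (minor) alleles at the
#' first and second locus, `A`/`B` the other alleles, so `p_ab` is the
#' frequency of the haplotype carrying the coded allele at both loci and
#' `p_a`, `p_b` are the marginal coded-allele frequencies.
#'
#' @param x A [geno_data] object.
#' @param snp_i,snp_j SNP ids or column indices.
#' @param tol Convergence tolerance on haplotype frequencies.
#' @return One-row tibble with `p_ab`, `p_aB`, `p_Ab`, `p_AB`, `p_a`,
#'   `p_b`, `n` (informative samples).
#' @export
em_haplotype_freqs <- function(x, snp_i, snp_j, tol = 1e-10) {
  i <- if (is.character(snp_i)) match(snp_i, x$map$snp_id) else snp_i
  j <- if (is.character(snp_j)) match(snp_j, x$map$snp_id) else snp_j
  cnt <- pair_geno_counts(x$genotypes, i, j)
  res <- em_hap_from_counts(cnt, tol = tol)
  if (res[1, "n"] < 2) {
    stop("fewer than 2 samples informative for this pair", call. = FALSE)
  }
  if (res[1, "p_a"] %in% c(0, 1) || res[1, "p_b"] %in% c(0, 1)) {
    stop("locus monomorphic in the pairwise-complete subset", call. = FALSE)
  }
  tibble::as_tibble(as.data.frame(res))
}

#' LD coefficients from haplotype frequencies
#'
#' Computes the disequilibrium coefficient `D = p_ab - p_a * p_b`,
#' Lewontin's normalised `D' = |D| / D_max` (with
#' `D_max = min(p_a * p_b, (1 - p_a)(1 - p_b))` for negative `D` and
#' `min(p_a (1 - p_b), (1 - p_a) p_b)` otherwise) and the squared allelic
#' correlation `r2 = D^2 / (p_a (1 - p_a) p_b (1 - p_b))`. Vectorised.
#'
#' @param p_a,p_b Marginal allele frequencies at the two loci, in (0, 1).
#' @param p_ab Frequency of the haplotype carrying both tracked alleles.
#' @return Tibble with `D`, `D_prime`, `r2`.
#' @export
#' @examples
#' ld_from_freqs(0.5, 0.5, 0.35)  # D = 0.10, D' = 0.4, r2 = 0.16
ld_from_freqs <- function(p_a, p_b, p_ab) {
  if (any(p_a <= 0 | p_a >= 1 | p_b <= 0 | p_b >= 1)) {
    stop("LD is undefined at a fixed locus (p_a or p_b in {0, 1})",
         call. = FALSE)
  }
  D <- p_ab - p_a * p_b
  d_max <- ifelse(D < 0,
                  pmin(p_a * p_b, (1 - p_a) * (1 - p_b)),
                  pmin(p_a * (1 - p_b), (1 - p_a) * p_b))
  tibble::tibble(
    D = D,
    D_prime = ifelse(d_max > 0, abs(D) / d_max, 0),
    r2 = D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  )
}

# Same-chromosome pair indices within max_distance_bp (half-open: the pair
# is kept when |bp_i - bp_j| < max_distance_bp, and always when
# max_distance_bp is Inf). Requires positions sorted within chromosome.
chrom_pair_indices <- function(map, max_distance_bp = Inf,
                               adjacent_only = FALSE) {
  ii <- integer(0); jj <- integer(0)
  for (chr in unique(map$chromosome)) {
    w <- which(map$chromosome == chr)
    w <- w[order(map$position_bp[w])]
    S <- length(w)
    if (S < 2L) next
    if (adjacent_only) {
      ii <- c(ii, w[-S]); jj <- c(jj, w[-1L])
      next
    }
    pos <- map$position_bp[w]
    upper <- if (is.finite(max_distance_bp)) {
      findInterval(pos + max_distance_bp - 0.5, pos)
    } else rep(S, S)
    cnt <- pmax(upper - seq_len(S), 0L)
    if (sum(cnt) == 0L) next
    ii <- c(ii, w[rep.int(seq_len(S), cnt)])
    jj <- c(jj, w[sequence(cnt, from = seq_len(S) + 1L)])
  }
  cbind(ii, jj)
}

#' Pairwise LD for same-chromosome SNP pairs
#'
#' Runs the two-locus EM for every same-chromosome pair closer than
#' `max_distance_bp` (or an explicit pair set) and returns D, D' and r2.
#' Pairs with fewer than 2 informative samples or a locus monomorphic in
#' the pairwise-complete subset get `NA` coefficients.
#'
#' @param x A [geno_data] object (positions sorted within chromosome).
#' @param pairs Optional two-column matrix of SNP column indices; default
#'   is all same-chromosome pairs within `max_distance_bp`.
#' @param max_distance_bp Pair inclusion cap, half-open (`distance < max`).
#' @param chunk_size Pairs processed per EM block (memory control).
#' @return Tibble: `chromosome`, `snp_i`, `snp_j`, `distance_bp`, `n`,
#'   `D`, `D_prime`, `r2`.
#' @export
ld_pairs <- function(x, pairs = NULL, max_distance_bp = Inf,
                     chunk_size = 200000L) {
  if (is.null(pairs)) {
    pairs <- chrom_pair_indices(x$map, max_distance_bp)
  }
  P <- nrow(pairs)
  res <- vector("list", max(1L, ceiling(P / chunk_size)))
  if (P == 0L) {
    return(tibble::tibble(chromosome = character(), snp_i = character(),
                          snp_j = character(), distance_bp = integer(),
                          n = integer(), D = double(), D_prime = double(),
                          r2 = double()))
  }
  starts <- seq.int(1L, P, by = chunk_size)
  for (k in seq_along(starts)) {
    rows <- starts[k]:min(starts[k] + chunk_size - 1L, P)
    ii <- pairs[rows, 1L]; jj <- pairs[rows, 2L]
    cnt <- pair_geno_counts(x$genotypes, ii, jj)
    em <- em_hap_from_counts(cnt)
    ok <- em[, "n"] >= 2 & em[, "p_a"] > 0 & em[, "p_a"] < 1 &
      em[, "p_b"] > 0 & em[, "p_b"] < 1
    D <- D_prime <- r2 <- rep(NA_real_, length(rows))
    if (any(ok)) {
      ld <- ld_from_freqs(em[ok, "p_a"], em[ok, "p_b"], em[ok, "p_ab"])
      D[ok] <- ld$D; D_prime[ok] <- ld$D_prime; r2[ok] <- ld$r2
    }
    res[[k]] <- tibble::tibble(
      chromosome = x$map$chromosome[ii],
      snp_i = x$map$snp_id[ii],
      snp_j = x$map$snp_id[jj],
      distance_bp = abs(x$map$position_bp[jj] - x$map$position_bp[ii]),
      n = as.integer(em[, "n"]),
      D = D, D_prime = D_prime, r2 = r2
    )
  }
  dplyr::bind_rows(res)
}

#' Windowed LD pruning
#'
#' Greedy r2-threshold pruning in sliding windows, as in chip-QC practice:
#' within each window of `window_snps` consecutive SNPs (map order, per
#' chromosome), while any retained pair has r2 above `r2_threshold`, the
#' pair with the highest r2 is found and its lower-MAF member removed (ties
#' broken by dropping the later map position); the window then shifts by
#' `step_snps`. r2 comes from the two-locus EM on the current dataset.
#'
#' @param x A post-QC [geno_data] object.
#' @param window_snps,step_snps Window size and shift, in SNPs.
#' @param r2_threshold Pairs above this r2 trigger a removal.
#' @return Character vector of retained SNP ids (map order).
#' @export
ld_prune <- function(x, window_snps = 50L, step_snps = 5L,
                     r2_threshold = 0.2) {
  maf <- snp_maf(x)
  keep <- rep(TRUE, n_snps(x))
  for (chr in unique(x$map$chromosome)) {
    w <- which(x$map$chromosome == chr)
    w <- w[order(x$map$position_bp[w])]
    S <- length(w)
    if (S < 2L) next
    starts <- seq.int(1L, S, by = step_snps)
    for (s in starts) {
      win <- w[s:min(s + window_snps - 1L, S)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      pr <- t(utils::combn(seq_along(win), 2L))
      cnt <- pair_geno_counts(x$genotypes, win[pr[, 1L]], win[pr[, 2L]])
      em <- em_hap_from_counts(cnt)
      r2 <- rep(NA_real_, nrow(pr))
      ok <- em[, "n"] >= 2 & em[, "p_a"] > 0 & em[, "p_a"] < 1 &
        em[, "p_b"] > 0 & em[, "p_b"] < 1
      if (any(ok)) {
        r2[ok] <- ld_from_freqs(em[ok, "p_a"], em[ok, "p_b"],
                                em[ok, "p_ab"])$r2
      }
      alive <- rep(TRUE, length(win))
      repeat {
        r2_alive <- r2
        r2_alive[!(alive[pr[, 1L]] & alive[pr[, 2L]])] <- NA_real_
        if (all(is.na(r2_alive)) || max(r2_alive, na.rm = TRUE) <= r2_threshold)
          break
        top <- which.max(r2_alive)
        cand <- win[c(pr[top, 1L], pr[top, 2L])]
        drop <- if (maf[cand[1L]] < maf[cand[2L]]) cand[1L]
                else if (maf[cand[2L]] < maf[cand[1L]]) cand[2L]
                else cand[which.max(x$map$position_bp[cand])]
        keep[drop] <- FALSE
        alive[match(drop, win)] <- FALSE
      }
    }
  }
  x$map$snp_id[keep]
}

ld_decay_breaks_kb <- c(0, 10, 20, 40, 60, 100, 200, 500, 1000)

ld_interval_labels <- function(breaks_kb = ld_decay_breaks_kb) {
  lo <- breaks_kb[-length(breaks_kb)]
  hi <- breaks_kb[-1L]
  sprintf("%g-%gkb", lo, hi)
}

#' Distance-binned LD decay table
#'
#' Computes r2 for all same-chromosome pairs closer than `max_distance_bp`,
#' bins pairs by inter-SNP distance into the standard chip intervals
#' (0-10, 10-20, 20-40, 40-60, 60-100, 100-200, 200-500, 500-1000 kb;
#' half-open `[lo, hi)`) and reports mean, SD and pair count per interval —
#' per population and for the pooled dataset (`"Total"`, computed on the
#' merged genotypes, not by averaging population means).
#'
#' @param x A post-QC autosomal [geno_data] object.
#' @param max_distance_bp Maximum pair distance (half-open), default 1 Mb.
#' @param by_population Also compute within each population label.
#' @param breaks_kb Interval edges in kb.
#' @return Tibble: `population`, `interval`, `n_pairs`, `mean_r2`, `sd_r2`.
#'   Empty intervals keep their row with `n_pairs = 0` and `NA` statistics.
#' @export
ld_decay_table <- function(x, max_distance_bp = 1e6, by_population = TRUE,
                           breaks_kb = ld_decay_breaks_kb) {
  groups <- list(Total = x)
  if (by_population && length(unique(x$samples$population)) > 1L) {
    groups <- c(split_populations(x), groups)
  }
  purrr::imap(groups, function(g, nm) {
    pd <- ld_pairs(g, max_distance_bp = min(max_distance_bp,
                                            max(breaks_kb) * 1000))
    bin_ld_pairs(pd, breaks_kb) |>
      dplyr::mutate(population = nm, .before = 1L)
  }) |>
    dplyr::bind_rows()
}

bin_ld_pairs <- function(pair_tbl, breaks_kb = ld_decay_breaks_kb) {
  labels <- ld_interval_labels(breaks_kb)
  pair_tbl <- dplyr::filter(pair_tbl, !is.na(.data$r2))
  idx <- findInterval(pair_tbl$distance_bp, breaks_kb * 1000,
                      rightmost.closed = FALSE)
  keep <- idx >= 1L & idx <= length(labels)
  tab <- tibble::tibble(interval = factor(labels[idx[keep]], levels = labels),
                        r2 = pair_tbl$r2[keep]) |>
    dplyr::group_by(.data$interval, .drop = FALSE) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_r2 = mean(.data$r2),
                     sd_r2 = stats::sd(.data$r2),
                     .groups = "drop")
  tab$mean_r2[tab$n_pairs == 0L] <- NA_real_
  tab$interval <- as.character(tab$interval)
  tab
}

#' Per-chromosome LD over adjacent SNP pairs
#'
#' Mean D' and r2 over consecutive-in-map SNP pairs for each chromosome,
#' with the mean/min/max adjacent-pair spacing in kb — the per-chromosome
#' summary conventional for chip LD reports.
#'
#' @param x A post-QC autosomal [geno_data] object.
#' @return Tibble: `chromosome`, `n_snps`, `mean_d_prime`, `mean_r2`,
#'   `mean_dist_kb`, `min_dist_kb`, `max_dist_kb`. Chromosomes with fewer
#'   than 2 SNPs report counts only.
#' @export
per_chromosome_ld <- function(x) {
  chroms <- unique(x$map$chromosome)
  chroms <- chroms[order(suppressWarnings(as.numeric(chroms)), chroms)]
  pairs <- chrom_pair_indices(x$map, adjacent_only = TRUE)
  pd <- ld_pairs(x, pairs = pairs)
  counts <- tibble::tibble(chromosome = chroms) |>
    dplyr::mutate(n_snps = vapply(
      .data$chromosome, function(ch) sum(x$map$chromosome == ch),
      integer(1), USE.NAMES = FALSE))
  if (nrow(pd)) {
    stats_tbl <- pd |>
      dplyr::group_by(.data$chromosome) |>
      dplyr::summarise(
        mean_d_prime = mean(.data$D_prime, na.rm = TRUE),
        mean_r2 = mean(.data$r2, na.rm = TRUE),
        mean_dist_kb = mean(.data$distance_bp) / 1000,
        min_dist_kb = min(.data$distance_bp) / 1000,
        max_dist_kb = max(.data$distance_bp) / 1000,
        .groups = "drop"
      )
  } else {
    stats_tbl <- tibble::tibble(
      chromosome = character(), mean_d_prime = double(),
      mean_r2 = double(), mean_dist_kb = double(),
      min_dist_kb = double(), max_dist_kb = double())
  }
  dplyr::left_join(counts, stats_tbl, by = "chromosome")
}
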