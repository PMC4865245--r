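# Small builders and independent oracles shared across the test files.

# Build a geno_data from a dosage matrix with a one-chromosome map.
tiny_geno <- function(g, chromosome = "1", position_bp = NULL,
                      population = "P1", allele_a = "A", allele_b = "G") {
  g <- as.matrix(g)
  m <- ncol(g)
  if (is.null(position_bp)) position_bp <- seq_len(m) * 1000L
  geno_data(
    g,
    map = tibble::tibble(
      snp_id = sprintf("s%d", seq_len(m)),
      chromosome = rep_len(chromosome, m),
      position_bp = as.integer(position_bp),
      allele_a = rep_len(allele_a, m),
      allele_b = rep_len(allele_b, m)
    ),
    samples = tibble::tibble(
      sample_id = sprintf("i%d", seq_len(nrow(g))),
      population = rep_len(population, nrow(g))
    )
  )
}

# Independent HWE oracle: full enumeration of the conditional heterozygote
# distribution using plain factorial weights (no shared code with
# hwe_exact_p, which uses a log-gamma formulation).
hwe_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  n_r <- min(2 * n_AA + n_AB, 2 * n_BB + n_AB)
  if (n_r == 0) return(1)
  hs <- seq(n_r %% 2, n_r, by = 2)
  w <- vapply(hs, function(h) {
    hom_r <- (n_r - h) / 2
    hom_c <- n - h - hom_r
    2^h * exp(lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
                lfactorial(hom_c))
  }, numeric(1))
  probs <- w / sum(w)
  obs <- probs[hs == n_AB]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Grid-search likelihood oracle for two-locus haplotype frequencies:
# profiles the coupling-haplotype frequency over its Frechet bounds with
# allele margins fixed at the observed frequencies (the EM conserves the
# margins), refining the grid three times.
grid_hap_oracle <- function(cnt) {
  n <- sum(cnt)
  # cnt: length-9 vector in (a, b) dosage order, a = locus-1 dosage
  a_dose <- rep(0:2, each = 3)
  b_dose <- rep(0:2, times = 3)
  p1 <- sum(cnt * a_dose) / (2 * n)
  p2 <- sum(cnt * b_dose) / (2 * n)
  loglik <- function(pbb) {
    pba <- p1 - pbb
    pab <- p2 - pbb
    paa <- 1 - p1 - p2 + pbb
    cell <- c(paa^2, 2 * paa * pab, pab^2,
              2 * paa * pba, 2 * (paa * pbb + pab * pba), 2 * pab * pbb,
              pba^2, 2 * pba * pbb, pbb^2)
    sum(cnt * log(pmax(cell, 1e-300)))
  }
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  for (step in c(1e-3, 1e-5, 1e-7)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, loglik, numeric(1))
    best <- grid[which.max(ll)]
    lo <- max(max(0, p1 + p2 - 1), best - step)
    hi <- min(min(p1, p2), best + step)
  }
  c(p_ab = best, p_a = p1, p_b = p2)
}

# Random two-locus genotype count table drawn from random haplotype
# frequencies under random mating.
random_geno_table <- function(n = 60) {
  repeat {
    p1 <- runif(1, 0.1, 0.9)
    p2 <- runif(1, 0.1, 0.9)
    lo <- max(0, p1 + p2 - 1)
    hi <- min(p1, p2)
    pbb <- runif(1, lo, hi)
    hap_p <- c(1 - p1 - p2 + pbb, p2 - pbb, p1 - pbb, pbb)  # AA, AB, BA, BB
    hap_dose <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
    h1 <- sample(4, n, replace = TRUE, prob = hap_p)
    h2 <- sample(4, n, replace = TRUE, prob = hap_p)
    x <- hap_dose[h1, 1] + hap_dose[h2, 1]
    y <- hap_dose[h1, 2] + hap_dose[h2, 2]
    if (length(unique(x)) > 1 && length(unique(y)) > 1) {
      # transpose so the vector runs in (a, b) order, b fastest
      return(as.vector(t(table(factor(x, 0:2), factor(y, 0:2)))))
    }
  }
}

# Independent greedy pruning oracle on one window covering all SNPs.
prune_oracle <- function(r2_mat, maf, pos, threshold = 0.2) {
  alive <- rep(TRUE, nrow(r2_mat))
  repeat {
    r2w <- r2_mat
    r2w[!alive, ] <- NA
    r2w[, !alive] <- NA
    diag(r2w) <- NA
    if (all(is.na(r2w)) || max(r2w, na.rm = TRUE) <= threshold) break
    top <- which(r2w == max(r2w, na.rm = TRUE), arr.ind = TRUE)[1, ]
    i <- min(top); j <- max(top)
    drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j
            else c(i, j)[which.max(pos[c(i, j)])]
    alive[drop] <- FALSE
  }
  which(alive)
}
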