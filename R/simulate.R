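# Genotype simulators with recorded truth. Every simulator is a pure
# function of its seed (bit-identical reruns) and returns
# list(dataset = <geno_data>, truth = <list>), the truth holding exactly
# the parameters needed to test the matching estimator by recovery.

#' Canonicalise allele coding to (major, minor)
#'
#' Recodes each SNP so that `allele_b` (the counted allele) is the minor
#' allele in the dataset, flipping dosages `x -> 2 - x` and swapping the
#' allele labels where needed; frequency ties are broken lexicographically
#' (`allele_a` becomes the lexicographically smaller allele). Datasets in
#' canonical coding survive a PED/MAP round trip bit-identically.
#'
#' @param x A [geno_data] object.
#' @return A recoded [geno_data].
#' @export
canonical_coding <- function(x) {
  p <- allele_freq(x)
  flip <- !is.na(p) & (
    p > 0.5 |
      (p == 0.5 & !is.na(x$map$allele_a) & !is.na(x$map$allele_b) &
         x$map$allele_a > x$map$allele_b)
  )
  if (any(flip)) {
    x$genotypes[, flip] <- 2L - x$genotypes[, flip]
    tmp <- x$map$allele_a[flip]
    x$map$allele_a[flip] <- x$map$allele_b[flip]
    x$map$allele_b[flip] <- tmp
  }
  # a monomorphic coded allele (p == 1 cannot occur after the flip, but
  # p == 0 with an unobserved b allele keeps its labels)
  x
}

# Evenly allocate n_snps across chromosomes and draw sorted unique
# positions along each.
sim_map <- function(n_snps, n_chrom, chrom_length_bp, spacing = NULL) {
  per <- rep(n_snps %/% n_chrom, n_chrom)
  extra <- n_snps %% n_chrom
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  pieces <- lapply(seq_len(n_chrom), function(ch) {
    if (is.null(spacing)) {
      pos <- sort(sample.int(chrom_length_bp, per[ch]))
    } else {
      pos <- seq.int(spacing, by = spacing, length.out = per[ch])
    }
    tibble::tibble(chromosome = as.character(ch), position_bp = pos)
  })
  map <- dplyr::bind_rows(pieces)
  map$snp_id <- sprintf("snp%d", seq_len(nrow(map)))
  map$allele_a <- "A"
  map$allele_b <- "G"
  map[, c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")]
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Discrete-generation, constant-size, random-mating Wright-Fisher
#' population: haplotypes recombine as a Poisson process along a linear
#' genetic map (`map_rate` Morgans per bp), no mutation during the
#' simulated window. Initial haplotypes are drawn site-independently at
#' chip-like frequencies (uniform on `[0.05, 0.5]`), so early generations
#' are near linkage equilibrium and LD accumulates by drift. SNPs
#' monomorphic at sampling time are retained (downstream QC removes
#' them). About `4 * N_diploid` generations are needed for the LD
#' pattern to equilibrate.
#'
#' @param N_diploid Population size (>= 10). A vector defines a stepwise
#'   size history: phase `i` runs at size `N_diploid[i]` for
#'   `n_generations[i]` generations (e.g. `N_diploid = c(200, 50)` with
#'   `n_generations = c(400, 50)` is a decline).
#' @param n_generations Generations to evolve (same length as
#'   `N_diploid`).
#' @param n_chrom,chrom_length_bp,n_snps Genome layout.
#' @param map_rate Morgans per bp (1e-8 = 1 cM/Mb).
#' @param sample_size Diploids sampled at the end (default all).
#' @param seed Integer seed.
#' @return `list(dataset, truth)`; `truth` records `true_ne`, the map
#'   rate and the scenario parameters.
#' @export
simulate_wright_fisher <- function(N_diploid = 100L,
                                   n_generations = 4L * N_diploid,
                                   n_chrom = 20L,
                                   chrom_length_bp = 5e6,
                                   n_snps = 2000L,
                                   map_rate = 1e-8,
                                   sample_size = N_diploid[length(N_diploid)],
                                   seed = 1L) {
  stopifnot(all(N_diploid >= 10L), length(n_generations) == length(N_diploid),
            sample_size <= N_diploid[length(N_diploid)])
  sizes <- rep.int(N_diploid, n_generations)
  withr::with_seed(seed, {
    map <- sim_map(n_snps, n_chrom, chrom_length_bp)
    chroms <- split(seq_len(nrow(map)), map$chromosome)
    chroms <- chroms[order(as.integer(names(chroms)))]

    N0 <- N_diploid[1L]
    H <- lapply(chroms, function(idx) {
      p0 <- stats::runif(length(idx), 0.05, 0.5)
      matrix(stats::rbinom(2L * N0 * length(idx), 1L,
                           rep(p0, each = 2L * N0)),
             nrow = 2L * N0)
    })
    L_m <- map_rate * chrom_length_bp   # genetic length, Morgans

    for (gen in seq_along(sizes)) {
      N_prev <- nrow(H[[1L]]) / 2L
      N_new <- sizes[gen]
      mothers <- sample.int(N_prev, N_new, replace = TRUE)
      fathers <- sample.int(N_prev, N_new, replace = TRUE)
      for (ch in seq_along(H)) {
        pos <- map$position_bp[chroms[[ch]]]
        g1 <- wf_gametes(H[[ch]], mothers, pos, L_m, chrom_length_bp)
        g2 <- wf_gametes(H[[ch]], fathers, pos, L_m, chrom_length_bp)
        Hn <- matrix(0L, 2L * N_new, length(pos))
        Hn[seq(1L, 2L * N_new, 2L), ] <- g1
        Hn[seq(2L, 2L * N_new, 2L), ] <- g2
        H[[ch]] <- Hn
      }
    }

    N_final <- sizes[length(sizes)]
    keep <- sort(sample.int(N_final, sample_size))
    geno <- do.call(cbind, lapply(H, function(h) {
      h[2L * keep - 1L, , drop = FALSE] + h[2L * keep, , drop = FALSE]
    }))
    ds <- canonical_coding(geno_data(
      geno, map = map,
      samples = tibble::tibble(sample_id = sprintf("wf%03d", keep),
                               population = "WF")
    ))
    list(
      dataset = ds,
      truth = list(scenario = "wright_fisher", true_ne = N_diploid,
                   n_generations = n_generations, map_rate = map_rate,
                   n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
                   sample_size = sample_size, seed = seed)
    )
  })
}

# One batch of gametes: each offspring draws a recombinant haplotype from
# its assigned parent. Crossover count ~ Poisson(genetic length);
# crossover positions uniform in physical coordinates (linear map).
wf_gametes <- function(H, parents, pos, L_m, chrom_length_bp) {
  G <- length(parents)
  start <- sample.int(2L, G, replace = TRUE) - 1L
  ncross <- stats::rpois(G, L_m)
  out <- H[2L * parents - 1L + start, , drop = FALSE]
  for (k in which(ncross > 0L)) {
    cx <- sort(stats::runif(ncross[k], 0, chrom_length_bp))
    hap <- (start[k] + findInterval(pos, cx)) %% 2L
    h1 <- H[2L * parents[k] - 1L, ]
    h2 <- H[2L * parents[k], ]
    out[k, ] <- ifelse(hap == 0L, h1, h2)
  }
  out
}

#' Balding-Nichols structured populations
#'
#' Drift-differentiated populations with known FST: ancestral frequencies
#' uniform on `[0.05, 0.95]`; each population's frequency is drawn from
#' `Beta(p (1 - F)/F, (1 - p)(1 - F)/F)` with `F = fst`; genotypes are
#' `Binomial(2, p_pop)`. SNPs are laid out on a chip-like map (29
#' autosomes, 50 kb spacing) but are statistically independent.
#'
#' @param n_pops,n_per_pop Number of populations and diploids per
#'   population.
#' @param fst Target differentiation, in (0, 1).
#' @param n_snps Number of SNPs.
#' @param seed Integer seed.
#' @return `list(dataset, truth)`; `truth` records `true_fst` and the
#'   ancestral and per-population frequencies.
#' @export
simulate_structured <- function(n_pops = 3L, fst = 0.12, n_per_pop = 30L,
                                n_snps = 5000L, seed = 1L) {
  stopifnot(fst > 0, fst < 1)
  withr::with_seed(seed, {
    map <- sim_map(n_snps, min(29L, n_snps), Inf, spacing = 50000L)
    p_anc <- stats::runif(n_snps, 0.05, 0.95)
    shape_scale <- (1 - fst) / fst
    p_pop <- sapply(seq_len(n_pops), function(k) {
      stats::rbeta(n_snps, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    })
    geno <- do.call(rbind, lapply(seq_len(n_pops), function(k) {
      matrix(stats::rbinom(n_per_pop * n_snps, 2L,
                           rep(p_pop[, k], each = n_per_pop)),
             nrow = n_per_pop)
    }))
    samples <- tibble::tibble(
      sample_id = sprintf("s%04d", seq_len(n_pops * n_per_pop)),
      population = rep(sprintf("P%d", seq_len(n_pops)), each = n_per_pop)
    )
    ds <- canonical_coding(geno_data(geno, map = map, samples = samples))
    list(
      dataset = ds,
      truth = list(scenario = "structured", true_fst = fst,
                   n_pops = n_pops, n_per_pop = n_per_pop,
                   ancestral_freqs = p_anc, pop_freqs = p_pop, seed = seed)
    )
  })
}

#' Pedigree gene-dropping with known kinship
#'
#' Simulates pairs of relatives by dropping founder alleles through the
#' minimal pedigree for the requested relationship, at independent SNPs
#' with founder frequencies drawn uniform on `[0.05, 0.5]` (chip-like)
#' unless supplied. Expected IBD sharing (`pi_hat`) is 0.5 for
#' parent-offspring and full sibs, 0.25 for half sibs and avuncular
#' pairs, 0.125 for first cousins, 0 for unrelated pairs.
#'
#' @param relationship One of `"parent-offspring"`, `"full-sib"`,
#'   `"half-sib"`, `"avuncular"`, `"first-cousin"`, `"unrelated"`.
#' @param n_pairs Number of independent pairs (2 samples each).
#' @param n_snps Number of SNPs (>= 1000 recommended for stable
#'   estimates).
#' @param founder_freqs Optional per-SNP founder allele frequencies.
#' @param seed Integer seed.
#' @return `list(dataset, truth)`; `truth` records `expected_pihat`,
#'   the founder frequency of each SNP's coded allele (`coded_freqs`) and
#'   the pair table.
#' @export
simulate_pedigree <- function(relationship = c("parent-offspring",
                                               "full-sib", "half-sib",
                                               "avuncular", "first-cousin",
                                               "unrelated"),
                              n_pairs = 100L, n_snps = 5000L,
                              founder_freqs = NULL, seed = 1L) {
  relationship <- match.arg(relationship)
  expected <- c(`parent-offspring` = 0.5, `full-sib` = 0.5,
                `half-sib` = 0.25, avuncular = 0.25,
                `first-cousin` = 0.125, unrelated = 0)[[relationship]]
  withr::with_seed(seed, {
    p <- founder_freqs %||% stats::runif(n_snps, 0.05, 0.5)
    stopifnot(length(p) == n_snps)

    founder <- function() {
      list(stats::rbinom(n_snps, 1L, p), stats::rbinom(n_snps, 1L, p))
    }
    gamete <- function(ind) {
      pick <- stats::rbinom(n_snps, 1L, 0.5)
      ifelse(pick == 1L, ind[[1L]], ind[[2L]])
    }
    child <- function(pa, ma) list(gamete(pa), gamete(ma))
    drop_pair <- function() {
      switch(relationship,
        "parent-offspring" = {
          f <- founder()
          list(f, child(f, founder()))
        },
        "full-sib" = {
          pa <- founder(); ma <- founder()
          list(child(pa, ma), child(pa, ma))
        },
        "half-sib" = {
          pa <- founder()
          list(child(pa, founder()), child(pa, founder()))
        },
        "avuncular" = {
          g1 <- founder(); g2 <- founder()
          a <- child(g1, g2); b <- child(g1, g2)
          list(a, child(b, founder()))
        },
        "first-cousin" = {
          g1 <- founder(); g2 <- founder()
          a <- child(g1, g2); b <- child(g1, g2)
          list(child(a, founder()), child(b, founder()))
        },
        "unrelated" = list(founder(), founder())
      )
    }

    geno <- matrix(0L, 2L * n_pairs, n_snps)
    for (k in seq_len(n_pairs)) {
      pr <- drop_pair()
      geno[2L * k - 1L, ] <- pr[[1L]][[1L]] + pr[[1L]][[2L]]
      geno[2L * k, ] <- pr[[2L]][[1L]] + pr[[2L]][[2L]]
    }
    ids <- sprintf("pair%04d_%d", rep(seq_len(n_pairs), each = 2L), 1:2)
    map <- sim_map(n_snps, min(29L, n_snps), Inf, spacing = 1000000L)
    ds <- canonical_coding(geno_data(
      geno, map = map,
      samples = tibble::tibble(sample_id = ids, population = "PED")
    ))
    pair_tbl <- tibble::tibble(
      id1 = sprintf("pair%04d_1", seq_len(n_pairs)),
      id2 = sprintf("pair%04d_2", seq_len(n_pairs))
    )
    list(
      dataset = ds,
      truth = list(scenario = "pedigree", relationship = relationship,
                   expected_pihat = expected, coded_freqs = p,
                   pairs = pair_tbl, seed = seed)
    )
  })
}

#' Admixed individuals with known ancestry fractions
#'
#' Cluster allele frequencies follow the Balding-Nichols model around
#' uniform `[0.05, 0.95]` ancestral frequencies with the given
#' between-ancestry FST; each individual's dosage is
#' `Binomial(2, sum_c q_c p_c)` for its ancestry row `q`.
#'
#' @param Q Matrix of ancestry fractions, one row per individual, rows
#'   summing to 1.
#' @param fst_between Differentiation between the ancestral clusters.
#' @param n_snps Number of SNPs.
#' @param seed Integer seed.
#' @return `list(dataset, truth)`; `truth` records `true_Q` and the
#'   cluster frequencies.
#' @export
simulate_admixed <- function(Q, fst_between = 0.2, n_snps = 2000L,
                             seed = 1L) {
  Q <- as.matrix(Q)
  stopifnot(all(abs(rowSums(Q) - 1) < 1e-8), all(Q >= 0))
  withr::with_seed(seed, {
    K <- ncol(Q); n <- nrow(Q)
    p_anc <- stats::runif(n_snps, 0.05, 0.95)
    ss <- (1 - fst_between) / fst_between
    P <- t(sapply(seq_len(K), function(k) {
      stats::rbeta(n_snps, p_anc * ss, (1 - p_anc) * ss)
    }))
    F1 <- Q %*% P
    geno <- matrix(stats::rbinom(n * n_snps, 2L, F1), n, n_snps)
    main <- apply(Q, 1L, which.max)
    samples <- tibble::tibble(
      sample_id = sprintf("adm%04d", seq_len(n)),
      population = sprintf("C%d", main)
    )
    map <- sim_map(n_snps, min(29L, n_snps), Inf, spacing = 50000L)
    ds <- canonical_coding(geno_data(geno, map = map, samples = samples))
    list(
      dataset = ds,
      truth = list(scenario = "admixed", true_Q = Q, cluster_freqs = P,
                   fst_between = fst_between, seed = seed)
    )
  })
}

#' Inject missing genotype calls
#'
#' Masks genotype cells independently with probability
#' `sample_rate[i] * snp_rate[k]` (rates recycled over samples and SNPs),
#' reproducibly under the seed. Used to exercise call-rate QC.
#'
#' @param x A [geno_data] object.
#' @param sample_rates,snp_rates Per-sample and per-SNP rate factors in
#'   `[0, 1]` (scalars recycled).
#' @param seed Integer seed.
#' @return A [geno_data] with additional `NA` calls.
#' @export
inject_missingness <- function(x, sample_rates = 0, snp_rates = 1,
                               seed = 1L) {
  n <- n_samples(x); m <- n_snps(x)
  sample_rates <- rep_len(sample_rates, n)
  snp_rates <- rep_len(snp_rates, m)
  stopifnot(all(sample_rates >= 0), all(sample_rates <= 1),
            all(snp_rates >= 0), all(snp_rates <= 1))
  withr::with_seed(seed, {
    prob <- outer(sample_rates, snp_rates)
    mask <- matrix(stats::runif(n * m) < prob, n, m)
    x$genotypes[mask] <- NA_integer_
  })
  x
}

#' Write / read a simulation truth sidecar
#'
#' Records the generative parameters of a simulated dataset as JSON next
#' to its PED/MAP pair.
#'
#' @param truth Truth list from a simulator.
#' @param path Output (input) path.
#' @return `write_truth` invisibly returns `truth`; `read_truth` returns
#'   the list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
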