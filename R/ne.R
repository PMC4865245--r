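#' Sampling-bias adjustment of r2
#'
#' Finite samples inflate r2 by about `1/(beta * n)`; the adjustment
#' subtracts it: `r2_adj = r2 - 1/(beta * n)`, with `beta = 2` for phased
#' haplotype data (2n haplotypes) and `beta = 1` for r2 estimated from n
#' unphased diploid genotypes. Floored at 0. Vectorised.
#'
#' @param r2 Squared correlation values.
#' @param n_samples Diploid sample count per value (>= 2).
#' @param phased Was r2 computed from phased haplotypes?
#' @return Adjusted r2 values.
#' @export
#' @examples
#' adjust_r2(0.5, 100)          # 0.49
#' adjust_r2(1 / 80, 80)        # 0: null LD fully absorbed
adjust_r2 <- function(r2, n_samples, phased = FALSE) {
  stopifnot(all(n_samples >= 2))
  beta <- if (phased) 2 else 1
  pmax(r2 - 1 / (beta * n_samples), 0)
}

#' Sved's recombination mapping
#'
#' Maps a recombination fraction c into the drift-recombination function
#' f(c) used by the LD-based Ne inversion. Default is Sved's mapping
#' `f(c) = c (1 - c/2) / (1 - c)^2`; `mapping = "identity"` uses
#' `f(c) = c` (both agree as c -> 0).
#'
#' @param c Recombination fraction, in (0, 0.5].
#' @param mapping `"sved"` or `"identity"`.
#' @return f(c), vectorised.
#' @export
#' @examples
#' sved_f(0.5)               # 1.5
#' sved_f(0.1, "identity")   # 0.1
sved_f <- function(c, mapping = c("sved", "identity")) {
  mapping <- match.arg(mapping)
  if (any(c <= 0)) stop("recombination fraction must be positive",
                        call. = FALSE)
  if (mapping == "identity") c else c * (1 - c / 2) / (1 - c)^2
}

#' Effective population size from binned LD
#'
#' Inverts the drift expectation of adjusted LD at recombination fraction
#' c: `Ne = (1 / (4 f(c))) * (1 / E[r2_adj] - alpha)`, paired with the
#' time horizon `t = 1/(2c)` generations ago. With the identity mapping
#' and matching alpha this is the exact algebraic inverse of
#' `E[r2_adj] = 1 / (alpha + 4 N c)`.
#'
#' @param mean_r2_adj Mean adjusted r2 in the bin (> 0).
#' @param c Recombination fraction of the bin (mean distance x map rate).
#' @param alpha The constant in the drift expectation (default 1).
#' @param mapping Passed to [sved_f()].
#' @return Ne estimate (vectorised); `NA` with a warning for bins where
#'   `1/mean_r2_adj <= alpha` (non-positive Ne).
#' @export
#' @examples
#' ne_at_bin(0.2, 0.0025, mapping = "identity")   # 400
ne_at_bin <- function(mean_r2_adj, c, alpha = 1,
                      mapping = c("sved", "identity")) {
  stopifnot(all(mean_r2_adj > 0))
  ne <- (1 / (4 * sved_f(c, mapping))) * (1 / mean_r2_adj - alpha)
  if (any(ne <= 0)) {
    warning(sprintf("%d bin(s) with 1/r2_adj <= alpha skipped (Ne <= 0)",
                    sum(ne <= 0)), call. = FALSE)
    ne[ne <= 0] <- NA_real_
  }
  ne
}

#' Configuration for the Ne trajectory
#'
#' @param n_bins Number of distance bins (default 20).
#' @param bin_width_bp Width of each bin in bp (default 50 kb, so the
#'   default grid tiles 0-1 Mb).
#' @param min_distance_bp,max_distance_bp Pair inclusion range (half-open).
#'   `max_distance_bp = NULL` uses `min + n_bins * bin_width`.
#' @param alpha Constant in the inversion (1 = drift-only expectation;
#'   2.2 corrects for mutation).
#' @param map_rate Morgans per bp (default 1e-8, i.e. 1 cM/Mb).
#' @param sved_mapping `"sved"` or `"identity"`.
#' @param phased Sampling-bias adjustment for phased data (see
#'   [adjust_r2()]).
#' @return A list of class `ne_config`.
#' @export
ne_config <- function(n_bins = 20L, bin_width_bp = 50000L,
                      min_distance_bp = 0L, max_distance_bp = NULL,
                      alpha = 1, map_rate = 1e-8,
                      sved_mapping = c("sved", "identity"),
                      phased = FALSE) {
  if (is.null(max_distance_bp)) {
    max_distance_bp <- min_distance_bp + n_bins * bin_width_bp
  }
  stopifnot(map_rate > 0, n_bins >= 1L,
            max_distance_bp > min_distance_bp)
  structure(
    list(n_bins = n_bins, bin_width_bp = bin_width_bp,
         min_distance_bp = min_distance_bp,
         max_distance_bp = max_distance_bp, alpha = alpha,
         map_rate = map_rate,
         sved_mapping = match.arg(sved_mapping), phased = phased),
    class = "ne_config"
  )
}

#' Historical effective population size from LD decay
#'
#' Computes r2 for all same-chromosome SNP pairs with inter-SNP distance
#' in `[min, max)`, adjusts each pair for sampling bias, bins pairs by
#' distance (default 20 bins of 50 kb), and converts each bin's mean
#' distance to a recombination fraction `c = map_rate * distance`, a time
#' horizon `t = 1/(2c)` generations ago and an Ne estimate via
#' [ne_at_bin()]. Deterministic given the dataset and configuration.
#'
#' @param x A post-QC autosomal [geno_data] object.
#' @param config An [ne_config()].
#' @return Tibble sorted by `t_generations` (ascending): `bin`,
#'   `mean_dist_bp`, `c`, `t_generations`, `n_pairs`, `mean_r2`,
#'   `mean_r2_adj`, `ne`. Empty bins are dropped.
#' @export
ne_trajectory <- function(x, config = ne_config()) {
  stopifnot(inherits(config, "ne_config"))
  pd <- ld_pairs(x, max_distance_bp = config$max_distance_bp)
  pd <- dplyr::filter(pd, !is.na(.data$r2),
                      .data$distance_bp >= config$min_distance_bp)
  if (!nrow(pd)) {
    stop("no informative SNP pairs in the distance range", call. = FALSE)
  }
  pd$r2_adj <- adjust_r2(pd$r2, pd$n, phased = config$phased)
  edges <- config$min_distance_bp +
    config$bin_width_bp * (0:config$n_bins)
  pd$bin <- findInterval(pd$distance_bp, edges, rightmost.closed = FALSE)
  pd <- dplyr::filter(pd, .data$bin >= 1L, .data$bin <= config$n_bins)

  out <- pd |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_dist_bp = mean(.data$distance_bp),
      n_pairs = dplyr::n(),
      mean_r2 = mean(.data$r2),
      mean_r2_adj = mean(.data$r2_adj),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      c = config$map_rate * .data$mean_dist_bp,
      t_generations = 1 / (2 * .data$c),
      ne = ifelse(.data$mean_r2_adj > 0,
                  suppressWarnings(
                    ne_at_bin(pmax(.data$mean_r2_adj, 1e-12), .data$c,
                              alpha = config$alpha,
                              mapping = config$sved_mapping)),
                  NA_real_)
    ) |>
    dplyr::arrange(.data$t_generations) |>
    dplyr::select("bin", "mean_dist_bp", "c", "t_generations", "n_pairs",
                  "mean_r2", "mean_r2_adj", "ne")
  out
}
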