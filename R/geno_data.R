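#' Construct a genotype dataset
#'
#' The canonical in-memory genotype model used throughout snppop: a diploid,
#' biallelic dosage matrix (samples x SNPs, values 0/1/2 counting copies of
#' `allele_b`, `NA` for missing calls) together with a SNP map and sample
#' metadata. `allele_b` is, by the package's coding convention, the minor
#' allele in the population the data were read from, so the minor allele
#' frequency of a SNP is `mean(dosage) / 2` in that population.
#'
#' @param genotypes Integer matrix, samples in rows and SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param map Data frame with columns `snp_id`, `chromosome` (character
#'   label; autosomes are `"1"`..`"29"`), `position_bp` (1-based physical
#'   position), `allele_a`, `allele_b` (single characters in A/C/G/T, or
#'   `NA` when unobserved at a monomorphic or fully missing locus).
#' @param samples Data frame with columns `sample_id` and `population`.
#'
#' @return An object of class `geno_data`.
#' @export
#' @examples
#' g <- geno_data(
#'   matrix(c(0L, 1L, 2L, NA), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("snp1", "snp2"))),
#'   map = tibble::tibble(snp_id = c("snp1", "snp2"), chromosome = "1",
#'                        position_bp = c(100L, 200L),
#'                        allele_a = "A", allele_b = "G"),
#'   samples = tibble::tibble(sample_id = c("s1", "s2"), population = "P1")
#' )
#' g
geno_data <- function(genotypes, map, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  map <- tibble::as_tibble(map)
  samples <- tibble::as_tibble(samples)

  stopifnot(
    all(c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b") %in%
          names(map)),
    all(c("sample_id", "population") %in% names(samples))
  )
  map$chromosome <- as.character(map$chromosome)
  map$position_bp <- as.integer(map$position_bp)

  if (nrow(samples) != nrow(genotypes) || nrow(map) != ncol(genotypes)) {
    stop("genotype matrix dimensions do not match sample/map tables",
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in dataset", call. = FALSE)
  }
  if (anyDuplicated(map$snp_id)) {
    stop("duplicate snp_id in dataset", call. = FALSE)
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- map$snp_id

  structure(
    list(genotypes = genotypes, map = map, samples = samples),
    class = "geno_data"
  )
}

#' @export
print.geno_data <- function(x, ...) {
  cat(sprintf(
    "<geno_data> %d samples x %d SNPs (%d population%s; %.2f%% missing)\n",
    n_samples(x), n_snps(x),
    length(unique(x$samples$population)),
    if (length(unique(x$samples$population)) == 1L) "" else "s",
    100 * mean(is.na(x$genotypes))
  ))
  invisible(x)
}

#' Number of samples / SNPs in a dataset
#' @param x A `geno_data` object.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$genotypes)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$genotypes)

#' Subset a genotype dataset
#'
#' `x[i, j]` keeps samples `i` and SNPs `j` (any standard index type,
#' including sample/SNP ids), returning a `geno_data`.
#'
#' @param x A `geno_data` object.
#' @param i,j Sample and SNP indices.
#' @param ... Ignored.
#' @export
`[.geno_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_snps(x))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$map$snp_id)
  geno_data(
    x$genotypes[i, j, drop = FALSE],
    map = x$map[j, , drop = FALSE],
    samples = x$samples[i, , drop = FALSE]
  )
}

#' Per-SNP allele frequency of the coded (b) allele
#'
#' @param x A `geno_data` object.
#' @return Named numeric vector, frequency of `allele_b` per SNP computed
#'   over non-missing genotypes (`NaN` where all calls are missing).
#' @export
allele_freq <- function(x) {
  colMeans(x$genotypes, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#'
#' @param x A `geno_data` object.
#' @return Named numeric vector `min(p, 1 - p)` of the coded-allele
#'   frequency `p`.
#' @export
snp_maf <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}

#' Split a dataset by population label
#'
#' @param x A `geno_data` object.
#' @return Named list of `geno_data`, one per population.
#' @export
split_populations <- function(x) {
  pops <- unique(x$samples$population)
  stats::setNames(
    lapply(pops, function(p) x[x$samples$population == p, ]),
    pops
  )
}
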