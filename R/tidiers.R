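#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an AMOVA result
#'
#' @param x A `snppop_amova` object.
#' @param ... Ignored.
#' @return The AMOVA table as a tibble (source, df, sums of squares,
#'   variance component, percentage of total).
#' @export
tidy.snppop_amova <- function(x, ...) x$table

#' One-row AMOVA summary
#'
#' @param x A `snppop_amova` object.
#' @param ... Ignored.
#' @return Tibble with `fst`, `p_value`, `n_permutations`.
#' @export
glance.snppop_amova <- function(x, ...) {
  tibble::tibble(fst = x$fst, p_value = x$p_value,
                 n_permutations = x$n_permutations)
}

#' Tidy PCA scores
#'
#' @param x A `snppop_pca` object.
#' @param ... Ignored.
#' @return The per-sample score tibble (`PC1`..`PCk` plus any sample
#'   metadata).
#' @export
tidy.snppop_pca <- function(x, ...) x$scores

#' One-row PCA summary
#'
#' @param x A `snppop_pca` object.
#' @param ... Ignored.
#' @return Tibble with one column per retained component's variance
#'   fraction.
#' @export
glance.snppop_pca <- function(x, ...) {
  tibble::as_tibble(as.list(stats::setNames(
    x$var_fraction, paste0("var_fraction_PC", seq_len(x$k)))))
}

#' Tidy admixture ancestry fractions
#'
#' @param x A `snppop_admixture` object.
#' @param ... Ignored.
#' @return Long tibble: `sample_id`, `population`, `cluster`, `fraction`.
#' @export
tidy.snppop_admixture <- function(x, ...) {
  tidyr::pivot_longer(x$Q, dplyr::starts_with("Q"),
                      names_to = "cluster", values_to = "fraction")
}

#' One-row admixture fit summary
#'
#' @param x A `snppop_admixture` object.
#' @param ... Ignored.
#' @return Tibble with `K`, `loglik`, `iterations`, `converged`.
#' @export
glance.snppop_admixture <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged)
}
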