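# ggplot2 views of the main result types. These are deliberately plain —
# publication cosmetics are left to the caller.

#' @describeIn pca_grm Scatter of two principal components, coloured by
#'   population when available.
#' @param object A `snppop_pca` object.
#' @param dims Which two components to plot.
#' @param ... Ignored.
#' @export
autoplot.snppop_pca <- function(object, dims = c(1L, 2L), ...) {
  d <- object$scores
  xv <- paste0("PC", dims[1L]); yv <- paste0("PC", dims[2L])
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[xv]], .data[[yv]]))
  if ("population" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$population))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", xv, 100 * object$var_fraction[dims[1L]]),
    y = sprintf("%s (%.1f%%)", yv, 100 * object$var_fraction[dims[2L]])
  )
}

#' @describeIn admixture_em Stacked ancestry bar plot, samples grouped by
#'   population.
#' @param object A `snppop_admixture` object.
#' @param ... Ignored.
#' @export
autoplot.snppop_admixture <- function(object, ...) {
  d <- tidy(object)
  d$sample_id <- factor(d$sample_id,
                        levels = unique(d$sample_id[order(d$population)]))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$fraction,
                                  fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~population, scales = "free_x", space = "free_x") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "ancestry fraction")
}

#' Plot an LD-decay table
#'
#' Mean r2 per distance interval, one line per population.
#'
#' @param decay Tibble from [ld_decay_table()].
#' @return A ggplot.
#' @export
plot_ld_decay <- function(decay) {
  decay$interval <- factor(decay$interval, levels = ld_interval_labels())
  ggplot2::ggplot(decay,
                  ggplot2::aes(.data$interval, .data$mean_r2,
                               colour = .data$population,
                               group = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "inter-SNP distance", y = expression(mean ~ r^2))
}

#' Plot an Ne trajectory
#'
#' Effective population size against generations ago, log-log.
#'
#' @param trajectory Tibble from [ne_trajectory()].
#' @return A ggplot.
#' @export
plot_ne_trajectory <- function(trajectory) {
  ggplot2::ggplot(dplyr::filter(trajectory, !is.na(.data$ne)),
                  ggplot2::aes(.data$t_generations, .data$ne)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations ago", y = expression(N[e]))
}
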