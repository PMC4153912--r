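#' Depth histogram of a run's molecule-tag categories
#'
#' The depth profile drives the accuracy/diversity trade-off: deep
#' categories give accurate consensus sequences, shallow ones capture more
#' of the template population.
#'
#' @param object An `mt_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_run <- function(object, ...) {
  ggplot2::ggplot(object$depth_histogram,
                  ggplot2::aes(x = .data$depth, y = .data$n_categories)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "MT depth (reads per tag)", y = "tag categories",
                  title = "Molecule-tag depth histogram") +
    ggplot2::theme_minimal()
}

#' Plot errors per base against category depth
#'
#' @param epb Depth-grouped EPB tibble from [evaluate_epb()]; several can be
#'   compared by binding rows with a `set` column.
#' @return A ggplot of mean EPB with standard-error bars by depth.
#' @export
plot_epb <- function(epb) {
  has_set <- "set" %in% names(epb)
  p <- ggplot2::ggplot(epb, ggplot2::aes(x = .data$depth, y = .data$mean_epb))
  if (has_set) {
    p <- p + ggplot2::aes(colour = .data$set, group = .data$set)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean_epb - .data$se, 0),
                                        ymax = .data$mean_epb + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "MT depth", y = "mean errors per base") +
    ggplot2::theme_minimal()
}
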