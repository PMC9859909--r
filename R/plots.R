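# ggplot2 displays for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an enrichment null distribution
#'
#' Histogram of the resampled null mean densities with the observed value
#' marked.
#'
#' @param object A `karyo_enrichment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot karyo_enrichment
#' @export
autoplot.karyo_enrichment <- function(object, ...) {
  df <- tibble(null = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "null mean density (proportion of bp)", y = "iterations",
      title = paste0(object$class %||% "element", " density in breakpoint windows"),
      subtitle = sprintf("observed %.4f vs null %.4f; two-tailed p = %.3g (%s)",
                         object$observed, object$null_mean, object$p,
                         object$direction)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a randomization-test null distribution
#'
#' @param object A `karyo_randtest`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot karyo_randtest
#' @export
autoplot.karyo_randtest <- function(object, ...) {
  df <- tibble(count = object$null_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar(fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "null overlap count", y = "iterations",
                  subtitle = sprintf("observed %d; empirical p = %.3g",
                                     object$observed, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot per-branch polarized event counts
#'
#' @param object A `karyo_polarized`.
#' @param ... Unused.
#' @return A ggplot of fusion/fission counts per branch.
#' @method autoplot karyo_polarized
#' @export
autoplot.karyo_polarized <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              -dplyr::all_of("branch"),
                              names_to = "type", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$branch, y = .data$n,
                                     fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(
      fusion = "firebrick", fission = "steelblue",
      ancestral_fusion = "salmon")) +
    ggplot2::labs(x = "branch", y = "events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dot-plot style view of synteny blocks
#'
#' Reference position against query position, one panel per reference
#' scaffold, coloured by query scaffold; breakpoints are where the colour
#' switches along a panel.
#'
#' @param blocks Block tibble from [build_blocks()].
#' @return A ggplot.
#' @export
plot_blocks <- function(blocks) {
  ggplot2::ggplot(blocks,
                  ggplot2::aes(x = .data$ref_start, xend = .data$ref_end,
                               y = .data$query_start, yend = .data$query_end,
                               colour = .data$query)) +
    ggplot2::geom_segment(linewidth = 1) +
    ggplot2::facet_wrap(~ref, scales = "free") +
    ggplot2::labs(x = "reference position (bp)", y = "query position (bp)",
                  colour = "query scaffold") +
    ggplot2::theme_minimal()
}
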