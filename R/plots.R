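# ggplot2 views of result tables.

#' Plot formation/resorption volume fractions across thresholds
#'
#' One panel per bone type x partition, fractions against density threshold,
#' formation and resorption as separate series, one line per interval.
#'
#' @param object A `remodeling_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot remodeling_result
#' @export
autoplot.remodeling_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("formation_fraction", "resorption_fraction"),
                              names_to = "direction", values_to = "fraction")
  long$direction <- sub("_fraction", "", long$direction)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$threshold, y = .data$fraction,
                               colour = .data$direction,
                               group = interaction(.data$direction,
                                                   .data$interval),
                               linetype = .data$interval)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(partition ~ bone_type) +
    ggplot2::labs(x = "density threshold (mg HA/cm³)",
                  y = "volume fraction", colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot BST-SNR by interval and casted status
#'
#' @param quality Quality tibble from [analyze_study()].
#' @return A ggplot.
#' @export
plot_quality <- function(quality) {
  ggplot2::ggplot(quality,
                  ggplot2::aes(x = .data$interval, y = .data$bst_snr,
                               fill = .data$casted)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "BST-SNR", x = NULL) +
    ggplot2::theme_minimal()
}

#' VIP profile of a fitted PLS report
#'
#' @param object A `pls_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pls_report
#' @export
autoplot.pls_report <- function(object, ...) {
  df <- object$variables
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vip, y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "VIP", y = NULL) +
    ggplot2::theme_minimal()
}
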