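# ggplot2 displays for the main result types.

#' Plot the B-vs-D functional-constraint comparison
#'
#' Boxplots of per-gene f values by CYP type, annotated with the
#' Mann-Whitney p-value.
#'
#' @param object a `cyp_type_comparison`
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.cyp_type_comparison <- function(object, ...) {
  ggplot2::ggplot(object$f_values,
                  ggplot2::aes(x = .data$cyp_type, y = .data$f,
                               fill = .data$cyp_type)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(B = "#4477AA", D = "#CC4444")) +
    ggplot2::labs(x = "CYP type", y = "f = sum(bN) / sum(bS)",
                  subtitle = sprintf("Mann-Whitney two-sided p = %.4g",
                                     object$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-site conservation along an alignment
#'
#' @param sites tibble from [conserved_sites()]
#' @param threshold the flagging threshold drawn as a horizontal line
#' @return a ggplot
#' @export
plot_site_conservation <- function(sites, threshold = 0.95) {
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$column,
                                      y = .data$conservation,
                                      fill = .data$flagged)) +
    ggplot2::geom_col(width = 1, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#CC4444",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "alignment position", y = "conservation") +
    ggplot2::theme_minimal()
}

#' Plot event rates per 100 myr
#'
#' @param rates tibble with columns `type` and `rate_per_100myr` (e.g. the
#'   pipeline `rates.tsv`)
#' @return a ggplot
#' @export
plot_event_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$type,
                                      y = .data$rate_per_100myr)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = NULL, y = "events per 100 myr") +
    ggplot2::theme_minimal()
}
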