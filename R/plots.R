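#' Bar chart of QC metrics
#'
#' @param object a `qc_report` tibble from [qc_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$numerator,
                                                    .data$denominator)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = "fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Positional-class composition of a classification table
#'
#' @param classes tibble from [classify_transcripts()].
#' @return a ggplot object.
#' @export
plot_positional_classes <- function(classes) {
  counts <- dplyr::count(classes, .data$positional_class, .data$novelty)
  ggplot2::ggplot(counts, ggplot2::aes(.data$positional_class, .data$n,
                                       fill = .data$novelty)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "transcripts", fill = "novelty") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
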