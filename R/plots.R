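#' Volcano plot of a DEP comparison
#'
#' log2 fold change against -log10 raw p-value, coloured by significance
#' call.
#'
#' @param records DEP tibble from [call_deps()].
#' @return a ggplot object.
#' @export
plot_volcano <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(.data$p_raw),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::labs(x = "log2 fold change (test / reference)",
                  y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Bar chart of inheritance-pattern counts
#'
#' @param calls pattern-call tibble from [classify_all()].
#' @return a ggplot object.
#' @export
plot_pattern_counts <- function(calls) {
  counts <- dplyr::count(calls, .data$label)
  counts$label <- factor(counts$label, levels = .pattern_labels)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar chart of qPCR relative expression
#'
#' Relative expression per genotype (calibrator level = 1, dashed line).
#'
#' @param rel tibble from [ddct_relative_expression()].
#' @return a ggplot object.
#' @export
plot_relative_expression <- function(rel) {
  ggplot2::ggplot(rel, ggplot2::aes(x = .data$genotype, y = .data$rel_expr)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "relative expression (2^-ddCt)",
                  title = unique(rel$gene)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object DEP tibble (for `autoplot`).
#' @param ... unused.
#' @method autoplot trio_report
#' @export
autoplot.trio_report <- function(object, ...) {
  plot_volcano(object$deps)
}
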