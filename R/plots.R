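#' Volcano plot of differential m6A calls
#'
#' @param object An `m6a_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot m6a_calls
#' @export
autoplot.m6a_calls <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "p_threshold")),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(attr(object, "fc_threshold")),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            none = "grey70")) +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = "-log10 p-value",
                  colour = NULL,
                  title = paste0("Differential m6A: ", attr(object, "metric"))) +
    ggplot2::theme_minimal()
}

#' Metagene profile plot over the 5'UTR | CDS | 3'UTR axis
#'
#' @param profile A [metagene_profile()] tibble.
#' @return A ggplot.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$axis_start, y = .data$density,
                                        fill = .data$region)) +
    ggplot2::geom_col(width = 1 / max(profile$bin)) +
    ggplot2::geom_vline(xintercept = c(1, 2), linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = c(0.5, 1.5, 2.5),
                                labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = NULL, y = "site density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of circRNA exon counts
#' @param hist An [exon_count_histogram()] tibble.
#' @return A ggplot.
#' @export
plot_exon_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$exon_count), y = .data$n)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::labs(x = "exons per circRNA", y = "count") +
    ggplot2::theme_minimal()
}

#' Bar chart of staged spliced lengths
#' @param hist A [length_histogram()] tibble.
#' @return A ggplot.
#' @export
plot_length_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_start, y = .data$n)) +
    ggplot2::geom_col(width = diff(c(hist$bin_start, max(hist$bin_end)))[1] * 0.9,
                      fill = "#16a085") +
    ggplot2::labs(x = "spliced length (bp)", y = "count") +
    ggplot2::theme_minimal()
}

#' Bar chart of the four m6A subgroup counts
#' @param counts A [subgroup_summary()] tibble.
#' @return A ggplot.
#' @export
plot_subgroups <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "#8e44ad") +
    ggplot2::labs(x = NULL, y = "circRNAs") +
    ggplot2::theme_minimal()
}
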