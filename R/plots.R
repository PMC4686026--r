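#' Plot haplotype frequencies
#'
#' Bar chart of per-haplotype relative frequencies with +/- 1 s.d. error
#' bars, optionally faceted by a grouping column when the input carries
#' per-sample rows.
#'
#' @param data Input accepted by [haplotype_frequencies()], or its output.
#' @return A ggplot object.
#' @export
plot_haplotype_frequencies <- function(data) {
  freq <- if (is.data.frame(data) && all(c("f", "sd") %in% names(data))) {
    data
  } else {
    haplotype_frequencies(data)
  }
  ggplot2::ggplot(freq, ggplot2::aes(
    x = stats::reorder(.data$haplotype, -.data$f), y = .data$f)) +
    ggplot2::geom_col(fill = "goldenrod") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$f - .data$sd, 0),
                                        ymax = .data$f + .data$sd),
                           width = 0.25) +
    ggplot2::labs(x = "haplotype", y = "frequency") +
    ggplot2::theme_minimal()
}
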