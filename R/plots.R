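# ggplot2 views of the main result types.

#' Heatmap of an OTU table
#'
#' Log10-scaled read-count heatmap, OTUs by samples -- the quickest way to
#' see spike-in bleed (faint off-sample cells in mock rows) before and
#' after filtering.
#'
#' @param table An OTU table tibble.
#' @return A ggplot object.
#' @export
plot_otu_heatmap <- function(table) {
  long <- tidyr::pivot_longer(validate_otu_table(table), -"otu_id",
                              names_to = "sample", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$otu_id,
                                     fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(reads + 1)") +
    ggplot2::labs(x = "sample", y = "OTU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a tag-switching estimate
#'
#' @param object A `bleed_estimate`.
#' @param ... Unused.
#' @return A ggplot bar chart of the directional and applied rates.
#' @export
autoplot.bleed_estimate <- function(object, ...) {
  df <- tibble(
    quantity = factor(c("into mock", "out of mock", "applied"),
                      levels = c("into mock", "out of mock", "applied")),
    pct = 100 * c(object$rate_in, object$rate_out, object$applied)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quantity, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(y = "tag-switching (%)", x = NULL,
                  title = sprintf("Spike-in sample '%s'", object$mock_sample)) +
    ggplot2::theme_minimal()
}

#' Length distribution of a sequence set
#'
#' @param seqs A reads tibble (or character vector).
#' @param binwidth Histogram bin width in bp (default 10).
#' @return A ggplot histogram of sequence lengths.
#' @export
plot_length_distribution <- function(seqs, binwidth = 10) {
  sq <- if (is.data.frame(seqs)) seqs$seq else as.character(seqs)
  df <- tibble(length = nchar(sq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "length (bp)", y = "sequences") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
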