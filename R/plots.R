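# ggplot2 views of the main result types.

#' Gel-style plot of band patterns
#'
#' Lanes are sequences, bands sit at their size-bin centers on a log scale
#' with the largest fragments at the top, as on an agarose gel.
#'
#' @param object An `ardra_bands` tibble from [band_pattern()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ardra_bands <- function(object, ...) {
  df <- as_tibble(object)
  if (!"seq_id" %in% names(df)) df$seq_id <- "pattern"
  df$lane <- factor(df$seq_id, levels = unique(df$seq_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lane, y = .data$bin_center)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = .data$count),
                       width = 0.7, height = 0.015, fill = "grey10") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_alpha_continuous(range = c(0.6, 1), guide = "none") +
    ggplot2::labs(x = NULL, y = "fragment size (bp)",
                  title = "In silico ARDRA band pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot a marker screen
#'
#' Percent identity per sequence, colored by classification, with the
#' restriction-site flag printed above each bar.
#'
#' @param object An `ardra_screen` from [screen_panel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ardra_screen <- function(object, ...) {
  df <- as_tibble(object)
  df$seq_id <- factor(df$seq_id, levels = df$seq_id)
  df$y <- ifelse(is.na(df$percent_identity), 0, df$percent_identity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$seq_id, y = .data$y,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$site), "",
                                                   .data$site)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% identity to reference marker",
                  fill = "call", title = "Marker screen") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
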