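#' Heatmap of a pairwise distance matrix
#' @param object A `paralog_dist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paralog_dist
#' @export
autoplot.paralog_dist <- function(object, ...) {
  td <- tidy(object)
  both <- bind_rows(td, dplyr::rename(td, label_a = "label_b", label_b = "label_a"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$label_a, y = .data$label_b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
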