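# ggplot2 views of the main result types.

#' Plot feature time courses
#'
#' @param tc A `tc_tbl`.
#' @param features Features to draw (default: first 6).
#' @return A ggplot.
#' @export
plot_timecourse <- function(tc, features = NULL) {
  features <- features %||% utils::head(tc$feature, 6)
  d <- tc[tc$feature %in% features, c("feature", tc_cols(tc))]
  long <- tidyr::pivot_longer(d, -"feature", names_to = "sample",
                              values_to = "value")
  long$zt <- as.numeric(stringr::str_match(long$sample,
                                           "^ZT([0-9]+\\.?[0-9]*)")[, 2])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$zt, y = .data$value,
                                     colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = tc_unit(tc),
                  colour = "feature")
}

#' Plot a PCA sample map
#'
#' @param pca Result of [pca_report()].
#' @return A ggplot with samples labelled by ZT, joined in time order.
#' @export
plot_pca <- function(pca) {
  d <- pca$scores[order(pca$scores$zt), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_path(colour = "grey60", linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = paste0("ZT", .data$zt)),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      title = sprintf("circular order score: %.2f",
                      pca$circular_score %||% NA_real_))
}
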