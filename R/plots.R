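# ggplot2 displays for the result types.

#' @export
autoplot.erf_map <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$scores)), times = ncol(object$scores)),
    col = rep(seq_len(ncol(object$scores)), each = nrow(object$scores)),
    score = as.vector(object$scores))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Effective receptive field: ",
                                 object$backbone, " (", object$variant, ")"),
                  x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scatter_compare <- function(object, ...) {
  thr <- attr(object, "threshold")
  pal <- c(red = "#d62728", blue = "#1f77b4", black = "grey20",
           tie = "#9467bd")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pcc_A, y = .data$pcc_B,
                               colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_vline(xintercept = thr, colour = "darkgreen",
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = thr, colour = "darkgreen",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0("Pcc (", attr(object, "model_A") %||% "A", ")"),
                  y = paste0("Pcc (", attr(object, "model_B") %||% "B", ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.encoding_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$roi, y = .data$pcc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        colour = "darkgreen", linetype = 2) +
    ggplot2::labs(x = "ROI", y = "Pearson correlation") +
    ggplot2::theme_minimal()
}
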