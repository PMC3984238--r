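#' Plot normalized LPCC scores with rejection thresholds
#'
#' One panel per (slice, shell): normalized LPCC against gradient direction,
#' the group's mean - n*sd threshold as a dashed line, rejected measurements
#' highlighted.
#'
#' @param object a `qc_report`.
#' @param slices optional subset of slices to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.qc_report <- function(object, slices = NULL, ...) {
  sc <- object$scores
  if (!is.null(slices)) sc <- dplyr::filter(sc, .data$slice %in% slices)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$direction_index,
                                   y = .data$lpcc_norm,
                                   colour = .data$rejected)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_grid(slice ~ bval, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "gradient direction", y = "normalized LPCC",
                  colour = "rejected") +
    ggplot2::theme_minimal()
}

#' Plot protocol-subset MSEs against the noise lower bound
#'
#' @param object an `mse_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mse_report <- function(object, ...) {
  s <- object$summary
  s$label <- factor(s$label, levels = unique(s$label))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$label, y = .data$mse_mean)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pass), size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mse_mean - .data$mse_sd,
                                        ymax = .data$mse_mean + .data$mse_sd),
                           width = 0.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$sigma2_L),
                        linetype = "dashed", colour = "blue") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 3, `FALSE` = 1)) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "protocol subset", y = "MSE",
                  shape = expression(MSE < sigma[L]^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot one axial slice of a parameter map
#'
#' @param map 3D array.
#' @param slice slice index.
#' @param name fill legend title.
#' @return a ggplot object.
#' @export
plot_map_slice <- function(map, slice = 1, name = "value") {
  m <- map[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$value <- m[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black", name = name) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
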