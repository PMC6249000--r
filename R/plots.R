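#' Heatmap of a connectivity matrix
#'
#' Plots the signed weight matrix as tiles, optionally reordering regions by
#' module so planted or detected block structure is visible.
#'
#' @param W Symmetric named numeric matrix.
#' @param partition Optional [module_partition()] used to order regions.
#' @return A ggplot object.
#' @export
plot_fc_matrix <- function(W, partition = NULL) {
  ids <- rownames(W)
  ord <- if (!is.null(partition)) {
    partition$region[order(partition$module)]
  } else ids
  df <- as_tibble(as.data.frame(as.table(W[ord, ord])), .name_repair = "minimal")
  names(df) <- c("row", "col", "weight")
  df$row <- factor(df$row, levels = ord)
  df$col <- factor(df$col, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @export
autoplot.module_partition <- function(object, W = NULL, ...) {
  if (!is.null(W)) return(plot_fc_matrix(W, object))
  sizes <- dplyr::count(tidy(object), .data$module)
  ggplot2::ggplot(sizes, ggplot2::aes(x = factor(.data$module),
                                      y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "module", y = "regions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stepwise_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$beta,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "grey75")) +
    ggplot2::labs(x = NULL, y = "standardized beta",
                  subtitle = sprintf("F(%d,%d) = %.2f, r2 = %.2f",
                                     object$df[1], object$df[2], object$F,
                                     object$r2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.null_dist <- function(object, observed = NULL, ...) {
  df <- tidy(object)
  g <- glance(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = c(g$t_lower, g$t_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "slope t statistic", y = "simulations") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "#b2182b")
  }
  p
}
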