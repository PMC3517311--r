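#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Null-distribution plot of a polarity test
#'
#' Histogram of the permutation null distances with the observed polarity
#' index marked.
#'
#' @param object A `polarity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polarity_result <- function(object, ...) {
  df <- tibble::tibble(null_d = object$null_d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_d)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$d, colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "normalized distance d (null patterns)", y = "count",
      title = sprintf("Nuclear polarity: d = %.3f, p = %.3f (n = %d centromeres)",
                      object$d, object$p_value, object$n_centromeres)) +
    ggplot2::theme_minimal()
}

#' Stage box plot of a per-nucleus metric
#'
#' @param data A data frame (e.g. `summaries` of a [run_pipeline()] result,
#'   or several row-bound ones) with a stage column.
#' @param value Name of the numeric column to plot.
#' @param stage Name of the stage column.
#' @return A ggplot object.
#' @export
plot_stage_boxplot <- function(data, value, stage = "stage") {
  stopifnot(value %in% names(data), stage %in% names(data))
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[stage]], y = .data[[value]])) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Middle z-slice of a stack with optional label contours
#'
#' Quick visual check of a segmentation: grey image of the central slice
#' with labelled objects overlaid as filled tiles.
#'
#' @param stack An [image_stack()].
#' @param labels Optional [label_map()] on the same grid.
#' @param z Slice index (default: middle).
#' @return A ggplot object.
#' @export
plot_slice <- function(stack, labels = NULL, z = NULL) {
  d <- dim(stack$voxels)
  z <- z %||% ((d[3] + 1L) %/% 2L)
  sl <- stack$voxels[, , z]
  df <- tidyr::expand_grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$intensity <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
  if (!is.null(labels)) {
    ll <- labels$labels[, , z]
    sel <- ll > 0
    if (any(sel)) {
      df2 <- df[as.vector(sel), c("y", "x")]
      df2$label <- factor(ll[sel])
      p <- p + ggplot2::geom_tile(data = df2,
                                  ggplot2::aes(colour = .data$label),
                                  fill = NA, linewidth = 0.2, show.legend = FALSE)
    }
  }
  p
}
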