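#' Plot a spectrogram
#'
#' Log-magnitude raster of the spectrogram, optionally overlaid with
#' detection or annotation boxes. Frames are thinned to at most `max_frames`
#' columns so multi-minute scenes stay plottable.
#'
#' @param object A `usv_spectrogram`.
#' @param boxes Optional tibble of boxes to draw.
#' @param max_frames Maximum number of frame columns drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usv_spectrogram <- function(object, boxes = NULL, max_frames = 1500,
                                     ...) {
  thin <- max(1L, ceiling(ncol(object$mag) / max_frames))
  fi <- seq(1L, ncol(object$mag), by = thin)
  df <- expand.grid(freq = object$bin_freqs / 1000,
                    time = object$frame_times[fi])
  df$db <- as.vector(20 * log10(pmax(object$mag[, fi], 1e-12)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                        fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (kHz)") +
    ggplot2::theme_minimal()
  if (!is.null(boxes) && nrow(boxes)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(boxes),
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = .data$f_low / 1000, ymax = .data$f_high / 1000),
      inherit.aes = FALSE, colour = "red", fill = NA, linewidth = 0.3
    )
  }
  p
}

#' Plot an evaluation report
#'
#' Per-file precision and recall as points over the across-file median.
#'
#' @param object A `usv_eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usv_eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_file[, c("file", "precision", "recall")],
    c("precision", "recall"), names_to = "metric"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, x = NULL,
                  title = sprintf("%s scoring", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot the inertia curve of a clustering model
#'
#' Within-cluster sum of squares against k, with the selected k marked.
#'
#' @param object A `usv_kmeans` carrying an `inertia_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usv_kmeans <- function(object, ...) {
  if (is.null(object$inertia_curve)) {
    stop("this clustering model carries no inertia curve")
  }
  ggplot2::ggplot(object$inertia_curve,
                  ggplot2::aes(.data$k, .data$inertia)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2, colour = "red") +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Tile plot of counts, true classes on rows.
#'
#' @param object A `usv_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usv_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(object$counts))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::theme_minimal()
}
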