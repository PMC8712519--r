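#' Tidy a confusion matrix
#'
#' One row per class with precision, recall and held-out count.
#'
#' @param x A `usv_confusion`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `n_true`, `precision`, `recall`.
#' @export
tidy.usv_confusion <- function(x, ...) {
  tibble::tibble(
    class = rownames(x$counts),
    n_true = rowSums(x$counts),
    precision = unname(x$precision),
    recall = unname(x$recall)
  )
}

#' @rdname tidy.usv_confusion
#' @export
glance.usv_confusion <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n)
}

#' @export
glance.usv_denoiser <- function(x, ...) {
  tibble::tibble(
    accuracy = x$holdout_accuracy, n_train = x$n_train, n_test = x$n_test,
    noise_recall = x$confusion$recall[["noise"]],
    call_recall = x$confusion$recall[["call"]]
  )
}

#' @export
glance.usv_classifier <- function(x, ...) {
  tibble::tibble(
    accuracy = x$holdout_accuracy, n_train = x$n_train, n_test = x$n_test,
    n_classes = length(x$classes)
  )
}

#' @export
tidy.usv_kmeans <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k), size = x$sizes),
    tibble::as_tibble(x$centroids)
  )
}

#' @export
glance.usv_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, n = length(x$assignments))
}

#' @export
tidy.usv_match <- function(x, ...) {
  x$detections
}

#' @export
glance.usv_match <- function(x, ...) {
  tibble::as_tibble(match_tally(x))
}

#' @export
tidy.usv_eval_report <- function(x, ...) {
  x$per_file
}

#' @export
glance.usv_eval_report <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary, names_from = "metric",
    values_from = c("mean", "median", "iqr"),
    names_glue = "{metric}_{.value}"
  ) |>
    dplyr::mutate(mode = x$mode, .before = 1)
}
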