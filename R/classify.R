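#' Train the supervised call-type classifier
#'
#' Fits a multiclass random-forest decision function over acoustic feature
#' vectors, assigning one of the repertoire call types to each detection.
#' Training uses a seeded stratified 8:2 learning/testing split; the held-out
#' confusion matrix ships with the model. Classes with fewer than 10 examples
#' trigger a warning but training proceeds -- the rarest natural call type
#' (the zip) is highly stereotyped and small samples of it are workable.
#'
#' @param features Tibble with the acoustic feature columns plus a `label`
#'   column of call-type names.
#' @param seed Integer seed (split + forest).
#' @param holdout_frac Testing fraction (default 0.2).
#' @param ntree Number of trees.
#' @return A `usv_classifier` object.
#' @export
train_classifier <- function(features, seed, holdout_frac = 0.2, ntree = 500) {
  fit_feature_classifier(
    features, seed,
    classes = NULL, min_per_class = 10L, min_action = "warn",
    holdout_frac = holdout_frac, ntree = ntree, class_name = "usv_classifier",
    balanced = TRUE
  )
}

#' @export
print.usv_classifier <- function(x, ...) {
  cat(sprintf(
    "<usv_classifier: %d classes, %d train / %d held out, accuracy %.3f>\n",
    length(x$classes), x$n_train, x$n_test, x$holdout_accuracy
  ))
  print(x$confusion$counts)
  invisible(x)
}

#' Classify detections by acoustic features
#'
#' Deterministic given model and features. Rows with missing features get an
#' `NA` label and zero scores.
#'
#' @param model A trained `usv_classifier`.
#' @param features Feature tibble (one row per detection). Must contain the
#'   feature columns the model was trained on.
#' @return A tibble with `label` and one `score_<class>` column per class
#'   (random-forest vote fractions); row order matches `features`. If
#'   `features` has a `detection_id` column it is carried through.
#' @export
classify_calls <- function(model, features) {
  stopifnot(inherits(model, "usv_classifier"))
  missing_cols <- setdiff(model$feature_cols, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks columns the model was trained on: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(features)
  scores <- matrix(0, n, length(model$classes),
                   dimnames = list(NULL, model$classes))
  label <- rep(NA_character_, n)
  if (n > 0L) {
    x <- features[, model$feature_cols, drop = FALSE]
    ok <- stats::complete.cases(x)
    if (any(ok)) {
      xd <- as.data.frame(x[ok, , drop = FALSE])
      pr <- predict(model$model, newdata = xd, type = "prob")
      scores[ok, colnames(pr)] <- pr
      label[ok] <- as.character(predict(model$model, newdata = xd))
    }
  }
  out <- tibble::tibble(label = label)
  colnames(scores) <- paste0("score_", colnames(scores))
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  if ("detection_id" %in% names(features)) {
    out <- dplyr::bind_cols(
      tibble::tibble(detection_id = features$detection_id), out
    )
  }
  out
}

#' Confusion matrix with per-class precision and recall
#'
#' Rows are true classes, columns predicted classes. Per-class precision is
#' the diagonal over the column sum, per-class recall the diagonal over the
#' row sum; micro-averaged recall equals the overall accuracy. Percentages in
#' the printed report are rounded to the nearest integer.
#'
#' @param true,predicted Equal-length label vectors.
#' @param classes Class list; defaults to the union of observed labels.
#'   Labels outside `classes` are an error.
#' @return A `usv_confusion` object: `counts` matrix, `precision`, `recall`
#'   (named vectors), `accuracy`, `n`.
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' cm$recall
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  if (length(true) != length(predicted)) {
    stop("label sequences must have equal length")
  }
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad)) {
    stop("labels outside the class list: ", paste(bad, collapse = ", "))
  }
  tf <- factor(true, levels = classes)
  pf <- factor(predicted, levels = classes)
  counts <- table(true = tf, predicted = pf)
  diagv <- diag(counts)
  col_sum <- colSums(counts)
  row_sum <- rowSums(counts)
  precision <- ifelse(col_sum > 0, diagv / col_sum, NA_real_)
  recall <- ifelse(row_sum > 0, diagv / row_sum, NA_real_)
  structure(
    list(
      counts = unclass(counts),
      precision = stats::setNames(as.double(precision), classes),
      recall = stats::setNames(as.double(recall), classes),
      accuracy = sum(diagv) / length(true), n = length(true)
    ),
    class = "usv_confusion"
  )
}

#' @export
print.usv_confusion <- function(x, ...) {
  cat(sprintf("<usv_confusion: n = %d, accuracy = %d%%>\n",
              x$n, round(100 * x$accuracy)))
  print(x$counts)
  cat("precision (%):",
      paste(names(x$precision), round(100 * x$precision), sep = "=",
            collapse = " "), "\n")
  cat("recall (%):   ",
      paste(names(x$recall), round(100 * x$recall), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}
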