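#' Doublet-syllable removal and fragment merging
#'
#' The cleanup filter for multi-detector output. Two passes:
#' 1. *Fragment merging* -- boxes from the same profile separated by gaps
#'    smaller than `merge_gap` are merged into one box spanning their union.
#' 2. *Doublet removal* -- a (merged) box whose temporal extent is at least
#'    `containment_frac` contained inside a box from a longer-duration profile
#'    is deleted (e.g. short-profile boxes around trill syllables sitting
#'    inside the long-profile trill box).
#'
#' Merging precedes deletion: in the other order, two partially contained
#' fragments could merge into a fully contained box that a second pass would
#' then delete, and the filter is required to be idempotent. The operation
#' never increases the box count.
#'
#' @param boxes Detection tibble from one audio file.
#' @param merge_gap Same-profile boxes closer than this (s) are merged.
#' @param containment_frac Containment fraction triggering doublet deletion.
#' @return Filtered detection tibble, sorted, with `status = "filtered"`.
#' @export
rds_filter <- function(boxes, merge_gap = 0.015, containment_frac = 0.9) {
  if (!nrow(boxes)) return(boxes)
  kept <- boxes |>
    dplyr::group_by(.data$source_detector) |>
    dplyr::group_modify(~ merge_adjacent(.x, merge_gap)) |>
    dplyr::ungroup()
  rank <- c(long = 3L, short = 2L, very_short = 1L)
  r <- rank[kept$source_detector]
  r[is.na(r)] <- 0L
  dur <- kept$t_end - kept$t_start
  n <- nrow(kept)
  drop <- logical(n)
  for (i in seq_len(n)) {
    higher <- which(r > r[i])
    if (!length(higher)) next
    ovl <- pmin(kept$t_end[higher], kept$t_end[i]) -
      pmax(kept$t_start[higher], kept$t_start[i])
    if (any(ovl / dur[i] >= containment_frac)) drop[i] <- TRUE
  }
  merged <- kept[!drop, , drop = FALSE]
  merged$status <- "filtered"
  merged <- dplyr::arrange(merged, .data$t_start, .data$detection_id)
  dplyr::relocate(
    merged, "detection_id", "t_start", "t_end", "f_low", "f_high",
    "score", "source_detector", "label", "status"
  )
}

# merge time-sorted boxes whose gap (t_start[i+1] - running end) < merge_gap
merge_adjacent <- function(df, merge_gap) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$t_start), , drop = FALSE]
  grp <- integer(nrow(df))
  g <- 1L
  run_end <- df$t_end[1]
  grp[1] <- g
  for (i in 2:nrow(df)) {
    if (df$t_start[i] - run_end < merge_gap) {
      run_end <- max(run_end, df$t_end[i])
    } else {
      g <- g + 1L
      run_end <- df$t_end[i]
    }
    grp[i] <- g
  }
  df |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      detection_id = dplyr::first(.data$detection_id),
      t_start = min(.data$t_start), t_end = max(.data$t_end),
      f_low = min(.data$f_low), f_high = max(.data$f_high),
      score = mean(.data$score),
      label = dplyr::first(.data$label), status = dplyr::first(.data$status),
      .groups = "drop"
    ) |>
    dplyr::select(-".grp")
}

#' Train the noise-vs-call classifier (denoiser)
#'
#' Fits a binary random-forest decision function over acoustic feature
#' vectors, separating true calls from detected noise events. A seeded
#' stratified 8:2 learning/testing split is drawn and the held-out confusion
#' matrix is reported with the model.
#'
#' @param features Tibble containing the acoustic feature columns plus a
#'   `label` column with values `"call"` and `"noise"`. Rows with missing
#'   features are dropped from training (an untrackable contour carries no
#'   usable evidence either way).
#' @param seed Integer seed: controls the split and the forest.
#' @param holdout_frac Testing fraction (default 0.2, the 8:2 convention).
#' @param ntree Number of trees.
#' @return A `usv_denoiser` model object with the held-out `confusion`
#'   matrix and per-class held-out accuracy.
#' @export
train_denoiser <- function(features, seed, holdout_frac = 0.2, ntree = 300) {
  fit_feature_classifier(
    features, seed,
    classes = c("call", "noise"), min_per_class = 20L,
    min_action = "error", holdout_frac = holdout_frac, ntree = ntree,
    class_name = "usv_denoiser"
  )
}

# shared fitting core for the denoiser and the call-type classifier;
# `balanced` draws a class-balanced bootstrap per tree so rare stereotyped
# classes (the zip) keep full recall against a confusable frequent class
fit_feature_classifier <- function(features, seed, classes = NULL,
                                   min_per_class, min_action,
                                   holdout_frac, ntree, class_name,
                                   balanced = FALSE) {
  stopifnot("label" %in% names(features))
  x <- features[, intersect(FEATURE_COLS, names(features)), drop = FALSE]
  if (!ncol(x)) stop("no acoustic feature columns found")
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  y <- as.character(features$label)[ok]
  if (!is.null(classes) && !all(y %in% classes)) {
    stop("labels outside the expected classes: ",
         paste(setdiff(unique(y), classes), collapse = ", "))
  }
  y <- factor(y, levels = if (is.null(classes)) sort(unique(y)) else classes)
  counts <- table(y)
  if (sum(counts > 0) < 2L) stop("need at least two classes to train")
  small <- counts[counts < min_per_class & counts > 0]
  if (length(small)) {
    msg <- paste0(
      "classes with fewer than ", min_per_class, " examples: ",
      paste(names(small), collapse = ", ")
    )
    if (min_action == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    test_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
      n_test <- max(1L, round(length(idx) * holdout_frac))
      sample(idx, n_test)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_along(y), test_idx)
    y_train <- droplevels(y[train_idx])
    rf_args <- list(
      x = as.data.frame(x[train_idx, , drop = FALSE]),
      y = y_train, ntree = ntree
    )
    if (balanced) {
      n_min <- min(table(y_train))
      rf_args$strata <- y_train
      rf_args$sampsize <- rep(n_min, nlevels(y_train))
    }
    rf <- do.call(randomForest::randomForest, rf_args)
    pred <- predict(rf, newdata = as.data.frame(x[test_idx, , drop = FALSE]))
    cm <- confusion_matrix(as.character(y[test_idx]), as.character(pred),
                           classes = levels(y))
    structure(
      list(
        model = rf, feature_cols = names(x), classes = levels(y),
        n_train = length(train_idx), n_test = length(test_idx),
        class_counts = as.list(counts), confusion = cm,
        holdout_accuracy = cm$accuracy, seed = as.integer(seed)
      ),
      class = class_name
    )
  })
}

#' @export
print.usv_denoiser <- function(x, ...) {
  cat(sprintf(
    "<usv_denoiser: %d train / %d held out, held-out accuracy %.3f>\n",
    x$n_train, x$n_test, x$holdout_accuracy
  ))
  print(x$confusion$counts)
  invisible(x)
}

classifier_predict <- function(model, features) {
  x <- features[, model$feature_cols, drop = FALSE]
  pred <- rep(NA_character_, nrow(x))
  ok <- stats::complete.cases(x)
  if (any(ok)) {
    pred[ok] <- as.character(
      predict(model$model, newdata = as.data.frame(x[ok, , drop = FALSE]))
    )
  }
  pred
}

#' Apply the denoiser to a detection table
#'
#' Boxes whose feature vector is classified as noise -- or whose contour was
#' untrackable (missing features) -- get `status = "rejected"`; the rest
#' become `"accepted"`. Nothing is deleted: rejected boxes remain in the
#' returned table as an audit trail, mirroring the reviewer's accept/reject
#' workflow.
#'
#' @param boxes Detection tibble.
#' @param features Feature tibble with one row per box, aligned by
#'   `detection_id` (or by position when ids are absent).
#' @param model A trained `usv_denoiser`.
#' @return The detection tibble with updated `status`.
#' @export
denoise <- function(boxes, features, model) {
  stopifnot(inherits(model, "usv_denoiser"))
  if (nrow(boxes) == 0L) return(boxes)
  if (nrow(features) != nrow(boxes)) {
    stop("need exactly one feature vector per box")
  }
  if ("detection_id" %in% names(features) &&
      "detection_id" %in% names(boxes)) {
    features <- features[match(boxes$detection_id, features$detection_id), ]
    if (anyNA(features$detection_id)) {
      stop("feature table does not cover all detection ids")
    }
  }
  pred <- classifier_predict(model, features)
  boxes$status <- ifelse(!is.na(pred) & pred == "call", "accepted", "rejected")
  boxes
}
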