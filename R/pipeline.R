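#' Pipeline configuration
#'
#' One serializable object holding every tunable of an end-to-end run. The
#' defaults reproduce the archive protocol's study conditions: 50 good-quality
#' units per call type and 10 units per type for the degraded standardized
#' scenarios (zips exist only in good quality), 3 s separators, 10
#' experimental sessions, 891 call + 598 noise denoiser examples, a
#' Table-shaped classifier training set, and k-means with up to 50 clusters
#' and 100 restarts. Tests and the acceptance script pass reduced counts; the
#' methods vignette states the desk-scale sizes used there.
#'
#' @param seed Global seed; every stage derives its seeds from it.
#' @param sample_rate Sampling rate (Hz).
#' @param window_length,overlap Spectrogram settings.
#' @param repertoire Named list of [call_type_spec]s.
#' @param noise_level_db Separator/bed noise level (dBFS RMS).
#' @param separator_duration Separator length (s).
#' @param clip_level,attenuation_db Degradation parameters.
#' @param standardized_units Named units-per-type counts for the four
#'   scenarios.
#' @param experimental_sessions Number of experimental scenes.
#' @param experimental_counts Units per call type in each experimental scene.
#' @param noise_events Broadband noise events per experimental scene.
#' @param denoiser_n Named counts `c(call=, noise=)` of denoiser training
#'   examples.
#' @param classifier_counts Named per-type counts of classifier training
#'   calls.
#' @param profiles Detector profiles, see [default_profiles()].
#' @param merge_gap,containment_frac Post-filter settings, see
#'   [rds_filter()].
#' @param iou_threshold Evaluation IoU threshold.
#' @param tonality_floor Contour cleaning floor.
#' @param max_clusters,replicates Clustering settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sample_rate = 192000,
                            window_length = 512 / 192000,
                            overlap = 0.5,
                            repertoire = default_repertoire(),
                            noise_level_db = -33,
                            separator_duration = 3,
                            clip_level = 0.5,
                            attenuation_db = -15,
                            standardized_units = c(good = 50, clipped = 10,
                                                   low_amplitude = 10,
                                                   overlaid = 10),
                            experimental_sessions = 10L,
                            experimental_counts = c(long_whistle = 4,
                                                    trill = 3,
                                                    short_whistle = 4,
                                                    tsak = 4, zip = 2),
                            noise_events = 6L,
                            denoiser_n = c(call = 891, noise = 598),
                            classifier_counts = c(trill = 302,
                                                  long_whistle = 186,
                                                  short_whistle = 1158,
                                                  tsak = 541, zip = 70),
                            profiles = default_profiles(),
                            merge_gap = 0.015,
                            containment_frac = 0.9,
                            iou_threshold = 0.5,
                            tonality_floor = 0.3,
                            max_clusters = 50L,
                            replicates = 100L) {
  check_sample_rate(sample_rate)
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic derived seeds; kept far below .Machine$integer.max
derive_seed <- function(config, stage, i = 0L) {
  (as.integer(config$seed) %% 10000L) * 100000L + stage * 1000L + i
}

#' Synthesize a labelled acoustic-feature training set
#'
#' Renders each requested call (and optionally broadband noise event)
#' individually over a noise bed, measures it through the spectrogram /
#' contour / feature chain using its ground-truth box, and returns the
#' feature table with labels -- the material used to train the denoiser and
#' the call-type classifier.
#'
#' @param counts Named vector: calls per call type.
#' @param n_noise Number of noise events (labelled `"noise"`).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param measure `"annotation"` measures each example through its
#'   ground-truth box (the convention for classifier training material);
#'   `"detection"` runs the detector on each rendered example and measures
#'   the best-overlapping detected box, mirroring how reviewer-marked
#'   detections are measured -- the denoiser is trained this way so that its
#'   training features live in the same measurement domain as the boxes it
#'   later judges (undetected examples are skipped).
#' @return Feature tibble with a `label` column.
#' @export
call_feature_set <- function(counts, n_noise = 0L, config = pipeline_config(),
                             seed = 1L,
                             measure = c("annotation", "detection")) {
  measure_mode <- match.arg(measure)
  sr <- config$sample_rate
  sigma <- 10^(config$noise_level_db / 20)
  pad <- round(if (measure_mode == "detection") 0.3 * sr else 0.05 * sr)
  measure <- function(samples, box) {
    n <- length(samples)
    clip <- usv_audio(rnorm(n + 2L * pad) * sigma, sr)
    clip$samples[pad + seq_len(n)] <- clip$samples[pad + seq_len(n)] + samples
    box$t_start <- box$t_start + pad / sr
    box$t_end <- box$t_end + pad / sr
    sg <- compute_spectrogram(clip, config$window_length, config$overlap)
    if (measure_mode == "detection") {
      det <- multi_detect(sg, config$profiles)
      if (!nrow(det)) return(NULL)
      ovl <- pmin(det$t_end, box$t_end) - pmax(det$t_start, box$t_start)
      if (max(ovl) <= 0) return(NULL)
      box <- as.list(det[which.max(ovl), c("t_start", "t_end",
                                           "f_low", "f_high")])
    }
    ctr <- tryCatch(
      extract_contour(sg, box, tonality_floor = config$tonality_floor),
      error = function(e) NULL
    )
    if (is.null(ctr) || nrow(ctr) == 0L) return(NULL)
    extract_features(ctr)
  }
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (ct in names(counts)) {
      cspec <- config$repertoire[[ct]]
      for (i in seq_len(counts[[ct]])) {
        cc <- render_call(cspec, sr)
        box <- list(t_start = cc$t_start, t_end = cc$t_end,
                    f_low = cc$f_low, f_high = cc$f_high)
        ft <- measure(cc$samples, box)
        if (!is.null(ft)) {
          ft$label <- ct
          rows <- c(rows, list(ft))
        }
      }
    }
    for (i in seq_len(n_noise)) {
      ne <- render_noise_event(sr)
      box <- as.list(ne$annotation[1, c("t_start", "t_end", "f_low", "f_high")])
      ft <- measure(ne$samples, box)
      if (!is.null(ft)) {
        ft$label <- "noise"
        rows <- c(rows, list(ft))
      }
    }
    dplyr::bind_rows(rows)
  })
}

# full per-file detection chain: detect -> denoise -> rds_filter
process_file <- function(clip, config, denoiser = NULL) {
  sg <- compute_spectrogram(clip, config$window_length, config$overlap)
  raw <- multi_detect(sg, config$profiles)
  feats <- extract_features_table(sg, raw,
                                  tonality_floor = config$tonality_floor)
  if (!is.null(denoiser) && nrow(raw)) {
    den <- denoise(raw, feats, denoiser)
    accepted <- den[den$status == "accepted", , drop = FALSE]
  } else {
    den <- raw
    accepted <- raw
  }
  filtered <- rds_filter(accepted, merge_gap = config$merge_gap,
                         containment_frac = config$containment_frac)
  list(raw = raw, denoised = den, accepted = accepted, filtered = filtered,
       features = feats, sgram_frames = ncol(sg$mag))
}

# render + process one standardized scenario for one call type
standardized_file_result <- function(config, scenario, call_type, denoiser,
                                     n_units, seed) {
  sp <- scene_spec(
    kind = "standardized", scenario = scenario, call_types = call_type,
    n_units = n_units, separator_duration = config$separator_duration,
    noise_level_db = config$noise_level_db, clip_level = config$clip_level,
    attenuation_db = config$attenuation_db, sample_rate = config$sample_rate,
    repertoire = config$repertoire, seed = seed
  )
  scene <- build_standardized_file(sp)
  res <- process_file(scene$clip, config, denoiser)
  res$annotations <- scene$annotations
  res$file <- paste(scenario, call_type, sep = "_")
  res
}

#' Train the denoiser from synthetic material
#'
#' Convenience wrapper: builds the labelled feature set ([call_feature_set()])
#' with the configured example counts (calls drawn evenly across the five
#' types) and fits the noise-vs-call model.
#'
#' @param config A [pipeline_config()].
#' @return A `usv_denoiser`.
#' @export
train_default_denoiser <- function(config = pipeline_config()) {
  n_call <- config$denoiser_n[["call"]]
  per_type <- table(rep(names(config$repertoire), length.out = n_call))
  feats <- call_feature_set(
    stats::setNames(as.integer(per_type), names(per_type)),
    n_noise = config$denoiser_n[["noise"]],
    config = config, seed = derive_seed(config, 1L),
    measure = "detection"
  )
  feats$label <- ifelse(feats$label == "noise", "noise", "call")
  train_denoiser(feats, seed = derive_seed(config, 2L))
}

#' Run the detection validation (model 1)
#'
#' End-to-end detection study on synthetic scenes: trains the denoiser,
#' renders the standardized files for every quality scenario (zips only in
#' good quality, as in the archive), runs detect -> denoise -> fragment
#' filter, and scores every scenario in automated and semi-automated mode.
#' Experimental mixed scenes are processed in three stages (raw detections,
#' after the denoiser, after the fragment filter) to quantify what each
#' cleanup step buys.
#'
#' @param config A [pipeline_config()].
#' @param denoiser Optionally a pre-trained `usv_denoiser` (trained if NULL).
#' @param verbose Print per-stage progress.
#' @return A `usv_model1` list: `scenario_summary`, `scenario_reports`,
#'   `step_table`, `experimental_reports`, `good_files` (kept for models 2
#'   and 3), `denoiser`, `config`.
#' @export
run_model1 <- function(config = pipeline_config(), denoiser = NULL,
                       verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(denoiser)) {
    say("training denoiser (%d call / %d noise examples)",
        config$denoiser_n[["call"]], config$denoiser_n[["noise"]])
    denoiser <- train_default_denoiser(config)
  }
  scenarios <- names(config$standardized_units)
  scenario_reports <- list()
  summary_rows <- list()
  good_files <- list()
  fi <- 0L
  for (scen in scenarios) {
    types <- names(config$repertoire)
    if (scen != "good") types <- setdiff(types, "zip")
    per_file <- list()
    for (ct in types) {
      fi <- fi + 1L
      res <- standardized_file_result(
        config, scen, ct, denoiser,
        n_units = config$standardized_units[[scen]],
        seed = derive_seed(config, 3L, fi)
      )
      say("standardized %s/%s: %d raw -> %d filtered boxes (%d true calls)",
          scen, ct, nrow(res$raw), nrow(res$filtered), nrow(res$annotations))
      per_file[[ct]] <- res
      if (scen == "good") good_files[[ct]] <- res
    }
    files <- tibble::tibble(
      file = vapply(per_file, `[[`, "", "file"),
      detections = lapply(per_file, `[[`, "filtered"),
      annotations = lapply(per_file, `[[`, "annotations")
    )
    scenario_reports[[scen]] <- list(
      automated = score_run(files, "automated", config$iou_threshold),
      semi_automated = score_run(files, "semi_automated",
                                 config$iou_threshold)
    )
    for (mode in c("automated", "semi_automated")) {
      s <- scenario_reports[[scen]][[mode]]$summary
      # scenarios are compared on across-type means (the robustness analysis
      # convention); medians/IQRs are kept for the session-level reports
      summary_rows <- c(summary_rows, list(tibble::tibble(
        scenario = scen, mode = mode,
        mean_precision = s$mean[s$metric == "precision"],
        mean_recall = s$mean[s$metric == "recall"],
        median_precision = s$median[s$metric == "precision"],
        median_recall = s$median[s$metric == "recall"],
        iqr_precision = s$iqr[s$metric == "precision"],
        iqr_recall = s$iqr[s$metric == "recall"]
      )))
    }
  }
  # experimental sessions: per-step scoring
  exp_files <- list()
  for (i in seq_len(config$experimental_sessions)) {
    sp <- scene_spec(
      kind = "experimental", scenario = "good",
      call_types = config$experimental_counts,
      noise_events = config$noise_events,
      noise_level_db = config$noise_level_db,
      sample_rate = config$sample_rate, repertoire = config$repertoire,
      seed = derive_seed(config, 4L, i)
    )
    scene <- build_experimental_scene(sp)
    res <- process_file(scene$clip, config, denoiser)
    res$annotations <- scene$annotations
    say("experimental %02d: %d raw / %d accepted / %d filtered (%d calls)",
        i, nrow(res$raw), nrow(res$accepted), nrow(res$filtered),
        sum(scene$annotations$call_type != "noise"))
    exp_files[[i]] <- res
  }
  step_files <- function(field) tibble::tibble(
    file = sprintf("session%02d", seq_along(exp_files)),
    detections = lapply(exp_files, `[[`, field),
    annotations = lapply(exp_files, `[[`, "annotations")
  )
  steps <- c(raw = "raw", denoised = "accepted", rds_filtered = "filtered")
  step_table <- dplyr::bind_rows(lapply(names(steps), function(st) {
    rep <- score_run(step_files(steps[[st]]), "automated",
                     config$iou_threshold)
    tibble::tibble(
      step = st,
      median_precision = rep$summary$median[rep$summary$metric == "precision"],
      median_recall = rep$summary$median[rep$summary$metric == "recall"]
    )
  }))
  experimental_reports <- list(
    automated = score_run(step_files("filtered"), "automated",
                          config$iou_threshold),
    semi_automated = score_run(step_files("filtered"), "semi_automated",
                               config$iou_threshold)
  )
  structure(
    list(
      scenario_summary = dplyr::bind_rows(summary_rows),
      scenario_reports = scenario_reports,
      step_table = step_table,
      experimental_reports = experimental_reports,
      good_files = good_files,
      denoiser = denoiser,
      config = config
    ),
    class = "usv_model1"
  )
}

#' @export
print.usv_model1 <- function(x, ...) {
  cat("<usv_model1: detection validation>\n")
  print(x$scenario_summary)
  cat("\nexperimental per-step (automated):\n")
  print(x$step_table)
  invisible(x)
}

# tp detections on the good standardized files with true labels + features
collect_detected_calls <- function(model1) {
  config <- model1$config
  rows <- list()
  for (ct in names(model1$good_files)) {
    res <- model1$good_files[[ct]]
    m <- match_detections(res$filtered, res$annotations,
                          iou_threshold = config$iou_threshold)
    tp <- m$detections[m$detections$category == "true_positive", ,
                       drop = FALSE]
    if (!nrow(tp)) next
    ann <- m$annotations
    feats <- res$features[match(tp$detection_id, res$features$detection_id), ]
    feats$true_type <- ann$call_type[match(tp$matched, ann$annotation_id)]
    feats$file <- res$file
    rows <- c(rows, list(feats))
  }
  dplyr::bind_rows(rows)
}

#' Run the supervised classification study (model 2)
#'
#' Trains the call-type classifier on synthetic good-quality calls and
#' applies it to the correctly detected calls of the good-quality
#' standardized files only (classification is scored on detections that hit a
#' true call, per the validation protocol). Reports the held-out confusion
#' matrix and per-type precision/recall of the applied classifier.
#'
#' @param config A [pipeline_config()].
#' @param model1 A `usv_model1` result to reuse detections from (computed
#'   fresh if NULL).
#' @param verbose Print progress.
#' @return A `usv_model2` list: `classifier`, `holdout_confusion`,
#'   `applied_confusion`, `per_type`, `detected_calls`, `config`.
#' @export
run_model2 <- function(config = pipeline_config(), model1 = NULL,
                       verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("rendering classifier training set (%d calls)",
      sum(config$classifier_counts))
  train_feats <- call_feature_set(config$classifier_counts, n_noise = 0L,
                                  config = config,
                                  seed = derive_seed(config, 5L))
  train_feats$label <- factor(train_feats$label,
                              levels = names(config$repertoire))
  clf <- train_classifier(train_feats, seed = derive_seed(config, 6L))
  if (is.null(model1)) model1 <- run_model1(config, verbose = verbose)
  calls <- collect_detected_calls(model1)
  pred <- classify_calls(clf, calls)
  applied <- confusion_matrix(calls$true_type, pred$label,
                              classes = clf$classes)
  per_file <- dplyr::bind_cols(calls, label = pred$label) |>
    dplyr::group_by(.data$file) |>
    dplyr::group_modify(function(df, key) {
      cm <- confusion_matrix(df$true_type, df$label, classes = clf$classes)
      tibble::tibble(call_type = clf$classes,
                     precision = cm$precision[clf$classes],
                     recall = cm$recall[clf$classes])
    }) |>
    dplyr::ungroup()
  iqr <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    unname(diff(quantile(v, c(0.25, 0.75))))
  }
  per_type <- per_file |>
    dplyr::group_by(.data$call_type) |>
    dplyr::summarise(
      median_precision = median(.data$precision, na.rm = TRUE),
      iqr_precision = iqr(.data$precision),
      median_recall = median(.data$recall, na.rm = TRUE),
      iqr_recall = iqr(.data$recall),
      .groups = "drop"
    )
  structure(
    list(classifier = clf, holdout_confusion = clf$confusion,
         applied_confusion = applied, per_type = per_type,
         detected_calls = dplyr::bind_cols(calls, predicted = pred$label),
         config = config),
    class = "usv_model2"
  )
}

#' @export
print.usv_model2 <- function(x, ...) {
  cat("<usv_model2: supervised classification>\n")
  cat(sprintf("held-out accuracy: %.3f | applied accuracy: %.3f\n",
              x$classifier$holdout_accuracy, x$applied_confusion$accuracy))
  print(x$per_type)
  invisible(x)
}

#' Run the unsupervised clustering study (model 3)
#'
#' Clusters the same correctly detected calls as the supervised study
#' (model 2) with equal frequency/duration/contour weights, selects k by the
#' elbow method, and cross-tabulates the clusters against the true call
#' types.
#'
#' @param config A [pipeline_config()].
#' @param model1 A `usv_model1` result to reuse detections from.
#' @param verbose Print progress.
#' @return A `usv_model3` list: `kmeans` (`usv_kmeans`), `k`, `inertia_curve`,
#'   `match` (contingency/mapping/coverage), `config`.
#' @export
run_model3 <- function(config = pipeline_config(), model1 = NULL,
                       verbose = FALSE) {
  if (is.null(model1)) model1 <- run_model1(config, verbose = verbose)
  calls <- collect_detected_calls(model1)
  x <- weighted_feature_matrix(calls)
  k <- choose_k_elbow(x, max_clusters = config$max_clusters,
                      replicates = config$replicates,
                      seed = derive_seed(config, 7L))
  km <- kmeans_cluster(x, as.integer(k), replicates = config$replicates,
                       seed = derive_seed(config, 8L),
                       inertia_curve = attr(k, "inertia"))
  kept <- attr(x, "kept")
  mm <- match_clusters_to_types(km$assignments, calls$true_type[kept])
  structure(
    list(kmeans = km, k = as.integer(k), inertia_curve = attr(k, "inertia"),
         match = mm, detected_calls = calls, config = config),
    class = "usv_model3"
  )
}

#' @export
print.usv_model3 <- function(x, ...) {
  cat(sprintf("<usv_model3: k-means clustering, elbow k = %d, %d calls>\n",
              x$k, length(x$kmeans$assignments)))
  print(x$match$mapping)
  invisible(x)
}
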