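test_that("precision and recall follow the defining count arithmetic", {
  expect_equal(round(precision_score(2, 12), 2), 0.14)
  expect_equal(precision_score(7, 0), 1.0)
  expect_equal(precision_score(0, 5), 0.0)
  expect_equal(precision_score(0, 0), 1.0)     # no detections, no mistakes
  expect_error(precision_score(-1, 2), "non-negative")

  expect_equal(recall_score(2, 2), 1.0)
  expect_equal(recall_score(0, 5), 0.0)
  expect_equal(round(recall_score(62, 63), 2), 0.98)
  expect_error(recall_score(3, 0), "undefined")
})

test_that("score functions agree with direct arithmetic on random tables", {
  withr::with_seed(14, {
    for (i in 1:200) {
      tp <- sample(0:50, 1)
      fp <- sample(0:50, 1)
      tt <- sample(1:60, 1)
      expect_equal(precision_score(tp, fp),
                   if (tp + fp == 0) 1 else tp / (tp + fp))
      expect_equal(recall_score(tp, tt), tp / tt)
    }
  })
})

test_that("matching assigns the full false-positive taxonomy", {
  anns <- dplyr::bind_rows(
    toy_ann(1.0, 1.1, "a1", "tsak", series_id = "s1"),
    toy_ann(1.2, 1.3, "a2", "tsak", series_id = "s1"),
    toy_ann(1.4, 1.5, "a3", "tsak", series_id = "s1"),
    toy_ann(3.0, 3.5, "a4", "long_whistle")
  )
  boxes <- dplyr::bind_rows(
    toy_box(0.95, 1.52, "cluster", "short"),   # spans the 3-tsak series
    toy_box(3.0, 3.5, "exact", "long"),        # exact true positive
    toy_box(5.0, 5.2, "noise", "short"),       # separator region
    toy_box(2.9, 3.1, "frag", "long")          # clipped piece of a4
  )
  m <- match_detections(boxes, anns)
  cat_of <- function(id) m$detections$category[m$detections$detection_id == id]
  expect_equal(cat_of("cluster"), "cluster_fp")
  expect_equal(strsplit(m$detections$matched[
    m$detections$detection_id == "cluster"], ",")[[1]],
    c("a1", "a2", "a3"))
  expect_equal(cat_of("exact"), "true_positive")
  expect_equal(cat_of("noise"), "noise_fp")
  expect_equal(cat_of("frag"), "fragment_fp")
  # partition: every detection in exactly one category
  tl <- glance(m)
  expect_equal(tl$tp + tl$fp, nrow(boxes))
})

test_that("a box over two cross-linked calls is an overlaid false positive", {
  anns <- dplyr::bind_rows(
    toy_ann(1.0, 1.5, "a1", "long_whistle", overlaid_with = "a2"),
    toy_ann(1.2, 1.7, "a2", "trill", overlaid_with = "a1")
  )
  boxes <- toy_box(1.0, 1.7, "d1", "long")
  m <- match_detections(boxes, anns)
  expect_equal(m$detections$category, "overlaid_fp")
  # semi-automated scoring credits both calls
  adj <- semi_automated_adjust(m)
  expect_equal(glance(adj)$tp, 2L)
  expect_equal(glance(adj)$recall, 1.0)
})

test_that("noise annotations are not matching targets", {
  anns <- dplyr::bind_rows(
    toy_ann(1.0, 1.1, "a1", "noise"),
    toy_ann(2.0, 2.2, "a2", "tsak")
  )
  boxes <- toy_box(1.0, 1.1, "onnoise")
  m <- match_detections(boxes, anns)
  expect_equal(m$tt, 1L)
  expect_equal(m$detections$category, "noise_fp")
  expect_error(match_detections(boxes, anns, iou_threshold = 0), "0, 1")
})

test_that("manual-correction simulation fixes fragments and clusters only", {
  anns <- dplyr::bind_rows(
    toy_ann(1.0, 1.1, "a1", "tsak"),
    toy_ann(1.2, 1.3, "a2", "tsak"),
    toy_ann(1.4, 1.5, "a3", "tsak"),
    toy_ann(3.0, 4.0, "a4", "long_whistle"),
    toy_ann(6.0, 6.4, "a5", "long_whistle")
  )
  boxes <- dplyr::bind_rows(
    toy_box(0.95, 1.52, "cl", "short"),    # cluster over the series
    toy_box(3.0, 3.4, "fr", "long"),       # fragment: 40% of a4
    toy_box(6.0, 6.4, "tp", "long"),       # clean true positive
    toy_box(8.0, 8.2, "nz", "short")       # noise
  )
  m <- match_detections(boxes, anns)
  adj <- semi_automated_adjust(m)
  tl <- glance(adj)
  expect_equal(tl$tp, 5L)                  # 3 split + 1 extended + 1 kept
  expect_equal(tl$noise_fp, 1L)            # noise is never corrected
  expect_equal(tl$recall, 1.0)
  # the extended fragment now spans its annotation exactly
  ext <- adj$detections[grepl("^fr_adj", adj$detections$detection_id), ]
  expect_equal(ext$t_start, 3.0)
  expect_equal(ext$t_end, 4.0)
  # conservation: ground truth untouched
  expect_equal(nrow(adj$annotations), nrow(m$annotations))

  # an input with only clean true positives is returned unchanged
  clean <- match_detections(boxes[3, ], anns)
  adj2 <- semi_automated_adjust(clean)
  expect_equal(glance(adj2)$tp, 1L)
  expect_equal(adj2$detections$t_start, 6.0)
})

test_that("mode dominance holds on matched scenes", {
  sc <- fixture_experimental()
  cfg <- pipeline_config(seed = 5)
  res <- usvpipe:::process_file(sc$clip, cfg, fixture_denoiser())
  files <- tibble::tibble(
    file = "s1", detections = list(res$filtered),
    annotations = list(sc$annotations)
  )
  auto <- score_run(files, "automated")
  semi <- score_run(files, "semi_automated")
  expect_gte(semi$summary$median[1], auto$summary$median[1])
  expect_gte(semi$summary$median[2], auto$summary$median[2])
})

test_that("score_run aggregates per-file and per-type results", {
  anns <- dplyr::bind_rows(
    toy_ann(1.0, 1.5, "a1", "long_whistle"),
    toy_ann(3.0, 3.1, "a2", "tsak")
  )
  boxes <- dplyr::bind_rows(
    toy_box(1.0, 1.5, "d1", "long"),
    toy_box(3.0, 3.1, "d2", "short")
  )
  files <- tibble::tibble(
    file = "f1", detections = list(boxes), annotations = list(anns)
  )
  rep <- score_run(files, "automated")
  expect_equal(rep$summary$median, c(1, 1))
  expect_equal(rep$summary$iqr, c(0, 0))
  expect_setequal(rep$per_type$call_type, c("long_whistle", "tsak"))
  expect_true(all(rep$per_type$median_recall == 1))

  # files without true calls are excluded from the recall summary
  empty_ann <- toy_ann(1, 1.1, "x", "noise")[0, ]
  files2 <- tibble::tibble(
    file = c("f1", "f2"),
    detections = list(boxes, boxes[0, ]),
    annotations = list(anns, empty_ann)
  )
  expect_warning(rep2 <- score_run(files2, "automated"), "without true calls")
  expect_equal(rep2$summary$median[rep2$summary$metric == "recall"], 1)
})

test_that("tidiers expose the report as tibbles", {
  anns <- toy_ann(1.0, 1.5, "a1", "long_whistle")
  boxes <- toy_box(1.0, 1.5, "d1", "long")
  files <- tibble::tibble(file = "f1", detections = list(boxes),
                          annotations = list(anns))
  rep <- score_run(files, "automated")
  expect_s3_class(tidy(rep), "tbl_df")
  g <- glance(rep)
  expect_equal(g$precision_median, 1)
  expect_equal(g$mode, "automated")
})
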