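# brute-force oracle for the merge-then-containment behaviour of rds_filter
oracle_rds <- function(boxes, merge_gap = 0.015, containment_frac = 0.9) {
  out <- list()
  for (src in unique(boxes$source_detector)) {
    b <- boxes[boxes$source_detector == src, ]
    b <- b[order(b$t_start), ]
    i <- 1
    while (i <= nrow(b)) {
      j <- i
      while (j < nrow(b) && b$t_start[j + 1] - max(b$t_end[i:j]) < merge_gap) {
        j <- j + 1
      }
      out <- c(out, list(tibble::tibble(
        t_start = b$t_start[i], t_end = max(b$t_end[i:j]),
        source_detector = src
      )))
      i <- j + 1
    }
  }
  m <- dplyr::bind_rows(out)
  rank <- c(long = 3, short = 2, very_short = 1)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (i == j) next
      if (rank[m$source_detector[j]] <= rank[m$source_detector[i]]) next
      ovl <- min(m$t_end[i], m$t_end[j]) - max(m$t_start[i], m$t_start[j])
      if (ovl / (m$t_end[i] - m$t_start[i]) >= containment_frac) {
        keep[i] <- FALSE
      }
    }
  }
  res <- m[keep, ]
  res[order(res$t_start), ]
}

random_boxes <- function(n) {
  src <- sample(c("long", "short", "very_short"), n, replace = TRUE)
  t0 <- runif(n, 0, 3)
  len <- ifelse(src == "long", runif(n, 0.2, 1),
                ifelse(src == "short", runif(n, 0.03, 0.15),
                       runif(n, 0.005, 0.025)))
  tibble::tibble(
    detection_id = sprintf("d%03d", seq_len(n)),
    t_start = t0, t_end = t0 + len, f_low = 10000, f_high = 30000,
    score = runif(n), source_detector = src, label = NA_character_,
    status = "raw"
  )
}

test_that("doublet boxes inside a longer-profile box are deleted", {
  boxes <- dplyr::bind_rows(
    toy_box(0.0, 1.0, "L1", "long"),
    toy_box(0.1, 0.2, "S1", "short"),
    toy_box(0.4, 0.5, "S2", "short")
  )
  out <- rds_filter(boxes)
  expect_equal(out$detection_id, "L1")
  expect_equal(out$status, "filtered")
})

test_that("same-profile fragments separated by small gaps are merged", {
  boxes <- dplyr::bind_rows(
    toy_box(0.10, 0.14, "S1", "short"),
    toy_box(0.15, 0.20, "S2", "short")
  )
  out <- rds_filter(boxes, merge_gap = 0.02)
  expect_equal(nrow(out), 1L)
  expect_equal(out$t_start, 0.10)
  expect_equal(out$t_end, 0.20)
})

test_that("disjoint boxes beyond the merge gap pass through untouched", {
  boxes <- dplyr::bind_rows(
    toy_box(0.1, 0.2, "S1", "short"),
    toy_box(0.5, 0.6, "S2", "short"),
    toy_box(1.0, 1.4, "L1", "long")
  )
  out <- rds_filter(boxes)
  expect_equal(nrow(out), 3L)
  expect_equal(out$t_start, c(0.1, 0.5, 1.0))
})

test_that("rds_filter is idempotent and never increases the box count", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      boxes <- random_boxes(sample(2:25, 1))
      once <- rds_filter(boxes)
      twice <- rds_filter(once)
      expect_lte(nrow(once), nrow(boxes))
      expect_equal(twice$t_start, once$t_start)
      expect_equal(twice$t_end, once$t_end)
    }
  })
})

test_that("rds_filter agrees with the brute-force interval oracle", {
  withr::with_seed(123, {
    for (rep in 1:200) {
      boxes <- random_boxes(sample(2:15, 1))
      got <- rds_filter(boxes)
      want <- oracle_rds(boxes)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$t_start, want$t_start, tolerance = 1e-12)
      expect_equal(got$t_end, want$t_end, tolerance = 1e-12)
    }
  })
})

test_that("the union of surviving boxes covers what the input covered", {
  # coverage preservation on random sets: every time point inside an input
  # box that survives deletion-by-containment must lie inside an output box
  withr::with_seed(7, {
    boxes <- random_boxes(20)
    out <- rds_filter(boxes)
    grid <- seq(0, 4, by = 0.001)
    covered_in <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(boxes))) {
      covered_in <- covered_in |
        (grid >= boxes$t_start[i] & grid <= boxes$t_end[i])
    }
    covered_out <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(out))) {
      covered_out <- covered_out |
        (grid >= out$t_start[i] & grid <= out$t_end[i])
    }
    # deleted boxes are >= 90% inside a surviving longer box, so at most the
    # uncontained slivers (10% of each deleted box) can lose coverage
    lost <- mean(covered_in & !covered_out) / mean(covered_in)
    expect_lte(lost, 0.1)
  })
})

test_that("the denoiser separates tonal calls from broadband noise", {
  den <- fixture_denoiser()
  expect_gte(den$confusion$recall[["call"]], 0.95)
  expect_gte(den$confusion$recall[["noise"]], 0.95)
})

test_that("denoiser training is deterministic and survives serialization", {
  fe <- fixture_features()
  fe$label <- ifelse(fe$label == "noise", "noise", "call")
  m1 <- train_denoiser(fe, seed = 301)
  m2 <- train_denoiser(fe, seed = 301)
  expect_identical(m1$confusion$counts, m2$confusion$counts)
  probe <- fe[sample.int(nrow(fe), 30), ]
  expect_identical(usvpipe:::classifier_predict(m1, probe),
                   usvpipe:::classifier_predict(m2, probe))
  # round trip through RDS leaves predictions unchanged
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m1, f)
  m1b <- readRDS(f)
  expect_identical(usvpipe:::classifier_predict(m1, probe),
                   usvpipe:::classifier_predict(m1b, probe))
})

test_that("shuffled labels bring the denoiser down to chance", {
  fe <- fixture_features()
  fe$label <- ifelse(fe$label == "noise", "noise", "call")
  # balance the classes so chance level is 0.5, then destroy the labels
  n_min <- min(table(fe$label))
  fe <- dplyr::slice_head(dplyr::group_by(fe, label), n = n_min)
  fe <- dplyr::ungroup(fe)
  accs <- vapply(1:4, function(i) {
    shuffled <- fe
    withr::with_seed(5 + i, shuffled$label <- sample(shuffled$label))
    train_denoiser(shuffled, seed = 302 + i)$holdout_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("single-class input is rejected", {
  fe <- fixture_features()
  fe$label <- "call"
  expect_error(train_denoiser(fe, seed = 1), "two classes")
})

test_that("denoise updates status and keeps the audit trail", {
  sc <- fixture_experimental()
  raw <- multi_detect(sc$sgram)
  feats <- extract_features_table(sc$sgram, raw)
  den <- denoise(raw, feats, fixture_denoiser())
  expect_equal(nrow(den), nrow(raw))
  expect_true(all(den$status %in% c("accepted", "rejected")))

  m <- match_detections(den, sc$annotations)
  noise_boxes <- m$detections$category == "noise_fp"
  call_boxes <- m$detections$category == "true_positive"
  expect_gte(mean(den$status[noise_boxes] == "rejected"), 0.8)
  expect_lte(mean(den$status[call_boxes] == "rejected"), 0.05)

  expect_error(denoise(raw, feats[-1, ], fixture_denoiser()), "one feature")
  expect_equal(nrow(denoise(raw[0, ], feats[0, ], fixture_denoiser())), 0L)
})

test_that("a model that never predicts noise passes every box through", {
  sc <- fixture_experimental()
  raw <- multi_detect(sc$sgram)
  feats <- extract_features_table(sc$sgram, raw)
  # a denoiser whose noise class lives absurdly far away predicts "call"
  # for every real feature vector
  fe <- fixture_features()
  fe$label <- "call"
  far <- fe[1:30, ]
  far[usvpipe:::FEATURE_COLS] <- far[usvpipe:::FEATURE_COLS] + 1e6
  far$label <- "noise"
  allcall <- train_denoiser(dplyr::bind_rows(fe, far), seed = 9)
  den <- denoise(raw, feats, allcall)
  ok <- stats::complete.cases(feats[usvpipe:::FEATURE_COLS])
  expect_true(all(den$status[ok] == "accepted"))
})

test_that("pipeline precision rises from raw through denoise and filtering", {
  sc <- fixture_experimental()
  cfg <- pipeline_config(seed = 5)
  res <- usvpipe:::process_file(sc$clip, cfg, fixture_denoiser())
  pr <- vapply(list(res$raw, res$accepted, res$filtered), function(b) {
    glance(match_detections(b, sc$annotations))$precision
  }, numeric(1))
  expect_true(all(diff(pr) >= 0))
  expect_gt(pr[3], pr[1])
})
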