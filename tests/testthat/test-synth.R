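test_that("a degenerate flat spec renders a pure tone at the set frequency", {
  spec <- call_type_spec("long_whistle", duration_range = c(0.5, 0.5),
                         f_start_range = c(25000, 25000),
                         contour_shape = "flat")
  s <- synth_call(spec, seed = 1, sample_rate = 192000)
  expect_equal(audio_duration(s$clip), 0.5, tolerance = 1e-3)
  sg <- compute_spectrogram(s$clip)
  mid <- which(sg$frame_times > 0.1 & sg$frame_times < 0.4)
  peaks <- sg$bin_freqs[apply(sg$mag[, mid], 2, which.max)]
  expect_true(all(abs(peaks - 25000) <= sg$bin_freqs[2]))
})

test_that("multi-syllable calls contain the requested number of energy bursts", {
  spec <- call_type_spec("trill", duration_range = c(0.08, 0.08),
                         f_start_range = c(20000, 20000),
                         contour_shape = "multi_syllable",
                         n_syllable_range = c(4L, 4L),
                         syllable_gap_range = c(0.02, 0.02),
                         fm_depth_range = c(4000, 4000),
                         fm_rate_range = c(30, 30))
  s <- synth_call(spec, seed = 2, sample_rate = 192000)
  # annotation covers 4 syllables + 3 gaps
  expect_gte(s$annotation$t_end - s$annotation$t_start, 4 * 0.07 + 3 * 0.02)
  # brute-force envelope thresholding finds exactly 4 disjoint bursts
  env <- abs(s$clip$samples)
  win <- 960L                      # 5 ms envelope smoothing
  env_s <- stats::filter(env, rep(1 / win, win), sides = 2)
  env_s[is.na(env_s)] <- 0
  bursts <- rle(as.vector(env_s) > 0.05 * max(env_s))
  expect_equal(sum(bursts$values), 4L)
})

test_that("synthesis is byte-identical under the same seed", {
  rep5 <- default_repertoire()
  a <- synth_call(rep5$trill, seed = 42)
  b <- synth_call(rep5$trill, seed = 42)
  expect_identical(a$clip$samples, b$clip$samples)
  expect_identical(a$annotation, b$annotation)
  c <- synth_call(rep5$trill, seed = 43)
  expect_false(identical(a$clip$samples, c$clip$samples))
})

test_that("sample rates below twice the band edge are rejected", {
  expect_error(synth_call(default_repertoire()$zip, 1, sample_rate = 96000),
               "at least")
})

test_that("every call type keeps >= 99% of its energy inside 5-50 kHz", {
  rep5 <- default_repertoire()
  for (ct in names(rep5)) {
    s <- synth_call(rep5[[ct]], seed = 7)
    x <- s$clip$samples
    sp <- Mod(stats::fft(x))^2
    freqs <- (seq_along(sp) - 1) / length(sp) * s$clip$sample_rate
    half <- freqs <= s$clip$sample_rate / 2
    in_band <- half & freqs >= 5000 & freqs <= 50000
    expect_gte(sum(sp[in_band]) / sum(sp[half]), 0.99)
  }
})

test_that("annotation boxes capture >= 90% of the rendered call energy", {
  rep5 <- default_repertoire()
  for (ct in names(rep5)) {
    s <- synth_call(rep5[[ct]], seed = 9)
    sr <- s$clip$sample_rate
    idx <- seq(max(1, round(s$annotation$t_start * sr)),
               min(length(s$clip$samples), round(s$annotation$t_end * sr)))
    expect_gte(sum(s$clip$samples[idx]^2) / sum(s$clip$samples^2), 0.90)
  }
})

test_that("standardized files have the expected layout and counts", {
  sc <- fixture_scene("long_whistle", n_units = 4)
  expect_equal(nrow(sc$annotations), 4L)
  call_time <- sum(sc$annotations$t_end - sc$annotations$t_start)
  expect_gte(audio_duration(sc$clip), 5 * 3 + call_time)
  expect_true(!is.unsorted(sc$annotations$t_start))

  # series types: one unit = three calls sharing a series id, gaps < 200 ms
  tk <- fixture_scene("tsak", n_units = 3)
  expect_equal(nrow(tk$annotations), 9L)
  expect_equal(length(unique(tk$annotations$series_id)), 3L)
  by_series <- split(tk$annotations, tk$annotations$series_id)
  for (s in by_series) {
    ici <- s$t_start[-1] - s$t_end[-nrow(s)]
    expect_true(all(ici < 0.2))
  }
})

test_that("degenerate scene requests are rejected", {
  expect_error(
    scene_spec("standardized", "good", call_types = character(0)),
    "exactly one"
  )
  expect_error(
    scene_spec("standardized", "overlaid", call_types = "tsak", n_units = 1),
    "two units"
  )
  expect_error(
    scene_spec("experimental", "good", call_types = c(5, 5)),
    "named count"
  )
})

test_that("experimental scenes place calls disjointly with exact truth", {
  sc <- fixture_experimental()
  ann <- sc$annotations
  calls <- ann[ann$call_type != "noise", ]
  noise <- ann[ann$call_type == "noise", ]
  expect_equal(nrow(calls), 2L * 3L + 2L * 3L + 2L + 2L + 2L)  # series expand
  expect_equal(nrow(noise), 5L)
  # pairwise disjoint call intervals
  calls <- calls[order(calls$t_start), ]
  expect_true(all(calls$t_start[-1] >= calls$t_end[-nrow(calls)]))

  # determinism: identical annotation tables under the same seed
  sp <- scene_spec("experimental", "good",
                   call_types = c(long_whistle = 2, trill = 2,
                                  short_whistle = 2, tsak = 2, zip = 2),
                   noise_events = 5, seed = 91)
  again <- build_experimental_scene(sp)
  expect_identical(again$annotations, sc$annotations)
  expect_identical(again$clip$samples, sc$clip$samples)
})

test_that("over-dense random-onset scenes are rejected with a message", {
  sp <- scene_spec("experimental", "good",
                   call_types = c(long_whistle = 30), duration = 8,
                   seed = 3)
  expect_error(build_experimental_scene(sp), "dense")
})

test_that("the sister-species variant is a two-syllable trill and idempotent", {
  rep5 <- default_repertoire()
  expect_error(sister_species_variant(rep5$zip), "trill")
  v <- sister_species_variant(rep5$trill)
  expect_equal(v$n_syllable_range, c(2L, 2L))
  expect_identical(sister_species_variant(v), v)
  # rendered variant produces two separable syllable boxes under detection
  s <- synth_call(v, seed = 5)
  bursts <- rle(abs(s$clip$samples) > 0.02 * max(abs(s$clip$samples)))
  expect_gte(sum(bursts$values), 2L)
})
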