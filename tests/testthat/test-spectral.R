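make_tone <- function(freq, dur = 0.05, sr = 192000, amp = 0.5) {
  usv_audio(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr)), sr)
}

test_that("spectrogram puts a pure tone's peak in the right bin everywhere", {
  sg <- compute_spectrogram(make_tone(25000))
  expect_lte(sg$bin_freqs[2] - sg$bin_freqs[1], 500)
  peaks <- sg$bin_freqs[apply(sg$mag, 2, which.max)]
  expect_true(all(abs(peaks - 25000) <= sg$bin_freqs[2]))
})

test_that("spectrogram of digital silence is identically zero", {
  sg <- compute_spectrogram(usv_audio(numeric(8000), 192000))
  expect_true(all(sg$mag == 0))
})

test_that("a rising chirp gives a monotone sequence of per-frame peaks", {
  sr <- 192000
  t <- seq(0, 1, by = 1 / sr)
  f_inst <- 10000 + 30000 * t / 2          # 10 -> 40 kHz linear chirp
  x <- usv_audio(0.5 * sin(2 * pi * cumsum(10000 + 30000 * t) / sr), sr)
  sg <- compute_spectrogram(x)
  peaks <- sg$bin_freqs[apply(sg$mag, 2, which.max)]
  inner <- peaks[10:(length(peaks) - 10)]
  expect_true(all(diff(inner) >= 0))
})

test_that("clips shorter than one window are rejected", {
  expect_error(compute_spectrogram(usv_audio(numeric(100), 192000)),
               "shorter than one")
})

test_that("tonality separates line spectra from flat spectra", {
  # constructed frames: one line among flat bins vs an exactly flat spectrum
  nb <- 64L
  line <- matrix(1e-6, nb, 1); line[20, 1] <- 1
  flat <- matrix(0.3, nb, 1)
  sg <- structure(
    list(mag = cbind(line, flat, 5 * line),
         bin_freqs = seq(0, 63) * 500, frame_times = c(0.01, 0.02, 0.03),
         window_length = 1 / 500, hop = 0.01, sample_rate = 64000),
    class = "usv_spectrogram"
  )
  expect_gt(tonality(sg, 1, band = c(0, 31500)), 0.9)
  expect_equal(tonality(sg, 2, band = c(0, 31500)), 0)
  # gain invariance
  expect_equal(tonality(sg, 3, band = c(0, 31500)),
               tonality(sg, 1, band = c(0, 31500)))
  expect_error(tonality(sg, 1, band = c(100000, 200000)), "empty")
})

test_that("contour over a tone is flat with no dropped frames", {
  clip <- make_tone(25000, dur = 0.1)
  sg <- compute_spectrogram(clip)
  box <- list(t_start = 0.01, t_end = 0.09, f_low = 20000, f_high = 30000)
  ctr <- extract_contour(sg, box)
  expect_gt(nrow(ctr), 0)
  expect_true(all(abs(ctr$peak_freq - 25000) <= sg$bin_freqs[2]))
  n_frames <- sum(sg$frame_times >= 0.01 & sg$frame_times <= 0.09)
  expect_equal(nrow(ctr), n_frames)
})

test_that("contour over pure noise is empty at a 0.5 tonality floor", {
  withr::with_seed(1, {
    clip <- usv_audio(rnorm(192000 / 5) * 0.05, 192000)
  })
  sg <- compute_spectrogram(clip)
  box <- list(t_start = 0.02, t_end = 0.18, f_low = 10000, f_high = 40000)
  ctr <- extract_contour(sg, box, tonality_floor = 0.5)
  expect_equal(nrow(ctr), 0)
})

test_that("silent gaps are dropped and contour times stay increasing", {
  sr <- 192000
  seg <- function(f, dur) 0.5 * sin(2 * pi * f * seq(0, dur, by = 1 / sr))
  x <- usv_audio(c(seg(20000, 0.05), numeric(round(0.03 * sr)),
                   seg(30000, 0.05)), sr)
  sg <- compute_spectrogram(x)
  box <- list(t_start = 0, t_end = 0.13, f_low = 15000, f_high = 35000)
  ctr <- extract_contour(sg, box)
  expect_true(all(diff(ctr$time) > 0))
  # no contour points inside the silent gap
  expect_false(any(ctr$time > 0.057 & ctr$time < 0.073))
})

test_that("features of canonical contours match closed forms", {
  sg <- compute_spectrogram(make_tone(25000, dur = 0.5))
  box <- list(t_start = 0.02, t_end = 0.48, f_low = 20000, f_high = 30000)
  f_flat <- extract_features(extract_contour(sg, box))
  expect_lt(abs(f_flat$slope), 2000)
  expect_equal(f_flat$sinuosity, 1, tolerance = 0.02)
  expect_lte(f_flat$bandwidth, 400)
  expect_equal(f_flat$pf_min <= f_flat$pf_mean &&
                 f_flat$pf_mean <= f_flat$pf_max, TRUE)

  # 10 -> 40 kHz chirp over 1 s: slope 30 kHz/s within 5%
  sr <- 192000
  t <- seq(0, 1, by = 1 / sr)
  chirp <- usv_audio(0.5 * sin(2 * pi * cumsum(10000 + 30000 * t) / sr), sr)
  sgc <- compute_spectrogram(chirp)
  boxc <- list(t_start = 0.01, t_end = 0.99, f_low = 9000, f_high = 41000)
  f_chirp <- extract_features(extract_contour(sgc, boxc))
  expect_lt(abs(f_chirp$slope - 30000) / 30000, 0.05)

  # sinusoidal FM bends the contour: sinuosity > 1
  fm <- usv_audio(0.5 * sin(2 * pi * cumsum(
    25000 + 6000 * sin(2 * pi * 40 * t)
  ) / sr), sr)
  sgf <- compute_spectrogram(fm)
  f_fm <- extract_features(extract_contour(
    sgf, list(t_start = 0.01, t_end = 0.99, f_low = 15000, f_high = 35000)
  ))
  expect_gt(f_fm$sinuosity, 1.5)
})

test_that("single-frame contours use the documented conventions", {
  ctr <- tibble::tibble(time = 0.01, peak_freq = 20000, peak_amp = 1,
                        tonality = 0.9)
  attr(ctr, "hop") <- 0.00133
  attr(ctr, "bin_width") <- 375
  class(ctr) <- c("usv_contour", class(ctr))
  f <- extract_features(ctr)
  expect_equal(f$duration, 0.00133)
  expect_equal(f$slope, 0)
  expect_equal(f$sinuosity, 1)
  expect_error(extract_features(ctr[0, ]), "empty")
})

test_that("contours recover the generating trajectory within 2 bin widths", {
  rep5 <- default_repertoire()
  for (ct in c("long_whistle", "tsak", "zip")) {
    s <- synth_call(rep5[[ct]], seed = 8)
    tr <- attr(s, "trajectory")
    sg <- compute_spectrogram(s$clip)
    ctr <- extract_contour(sg, s$annotation)
    truef <- stats::approx(tr$time, tr$freq, xout = ctr$time, rule = 2)$y
    mae <- mean(abs(ctr$peak_freq - truef))
    expect_lte(mae, 2 * (sg$bin_freqs[2] - sg$bin_freqs[1]))
  }
})

test_that("feature extraction is deterministic given a contour", {
  sc <- fixture_scene("tsak", n_units = 3)
  ctr <- extract_contour(sc$sgram, sc$annotations[1, ])
  expect_identical(extract_features(ctr), extract_features(ctr))
})
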