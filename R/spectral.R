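#' Short-time magnitude spectrogram
#'
#' Computes a Hann-windowed short-time Fourier magnitude matrix. Frames are
#' processed in chunks so multi-minute 192 kHz scenes keep a bounded memory
#' footprint. At the default window (512 samples at 192 kHz, 50% overlap) the
#' frequency resolution is 375 Hz, comfortably inside the 500 Hz contract the
#' downstream measurements assume.
#'
#' @param clip A [usv_audio] object.
#' @param window_length Analysis window length in seconds (default: 512
#'   samples at 192 kHz). The window must cover at least 8 samples.
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return A `usv_spectrogram`: list with `mag` (frequency-bin x frame
#'   magnitude matrix), `bin_freqs`, `frame_times` (frame centres, s),
#'   `window_length`, `hop` (s) and `sample_rate`.
#' @export
compute_spectrogram <- function(clip, window_length = 512 / 192000,
                                overlap = 0.5) {
  stopifnot(inherits(clip, "usv_audio"))
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  sr <- clip$sample_rate
  n <- round(window_length * sr)
  if (n < 8) stop("window must cover at least 8 samples")
  if (length(clip$samples) < n) {
    stop("clip shorter than one analysis window")
  }
  hop <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(clip$samples) - n + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  nb <- n %/% 2 + 1L
  mag <- matrix(0, nb, length(starts))
  chunk <- 4096L
  offs <- 0:(n - 1)
  for (i0 in seq(1L, length(starts), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(starts))
    fr <- matrix(clip$samples[outer(offs, starts[idx], "+")], nrow = n) * w
    mag[, idx] <- abs(stats::mvfft(fr)[seq_len(nb), , drop = FALSE])
  }
  structure(
    list(
      mag = mag,
      bin_freqs = (seq_len(nb) - 1L) * sr / n,
      frame_times = (starts - 1 + n / 2) / sr,
      window_length = n / sr, hop = hop / sr, sample_rate = sr
    ),
    class = "usv_spectrogram"
  )
}

#' @export
print.usv_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<usv_spectrogram: %d bins x %d frames, df %.0f Hz, hop %.2f ms>\n",
    nrow(x$mag), ncol(x$mag), x$bin_freqs[2] - x$bin_freqs[1], 1000 * x$hop
  ))
  invisible(x)
}

band_bins <- function(sgram, band) {
  idx <- which(sgram$bin_freqs >= band[1] & sgram$bin_freqs <= band[2])
  if (!length(idx)) stop("frequency band is empty for this spectrogram")
  idx
}

# Per-frame tonality over a band for all frames at once: 1 - spectral flatness
# of the in-band power spectrum, Bartlett-smoothed over 3 adjacent bins. The
# smoothing stabilises the geometric mean of raw periodogram bins (whose
# single-bin variance would let pure noise frames fluctuate above 0.5) without
# changing the limits: exactly 0 for a flat spectrum, -> 1 for a line
# spectrum; all-zero frames score 0. Invariant to overall gain.
tonality_frames <- function(sgram, band = USV_BAND) {
  bi <- band_bins(sgram, band)
  p <- sgram$mag[bi, , drop = FALSE]^2
  if (length(bi) >= 3L) {
    n <- nrow(p)
    ps <- p
    ps[2:(n - 1), ] <- (p[1:(n - 2), ] + p[2:(n - 1), ] + p[3:n, ]) / 3
    ps[1, ] <- (p[1, ] + p[2, ]) / 2
    ps[n, ] <- (p[n - 1, ] + p[n, ]) / 2
    p <- ps
  }
  am <- colMeans(p)
  tiny <- 1e-300
  gm <- exp(colMeans(log(pmax(p, tiny))))
  out <- 1 - gm / pmax(am, tiny)
  out[am <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Tonality of one spectrogram frame
#'
#' Tonality quantifies how line-like (versus noise-like) a spectral frame is
#' within a band, and is used both to gate detections and to clean contours.
#' It is defined as one minus the spectral flatness (ratio of geometric to
#' arithmetic mean of the in-band power spectrum, Bartlett-smoothed over three
#' adjacent bins for variance stabilisation): exactly 0 for a flat spectrum,
#' approaching 1 for a single spectral line. Without the smoothing, raw
#' periodogram variability would let pure white-noise frames score above 0.5.
#'
#' @param sgram A `usv_spectrogram`.
#' @param frame_index Frame number (column of the magnitude matrix).
#' @param band Frequency interval `c(low, high)` in Hz.
#' @return Tonality score in `[0, 1]`.
#' @export
tonality <- function(sgram, frame_index, band = USV_BAND) {
  stopifnot(inherits(sgram, "usv_spectrogram"))
  stopifnot(frame_index >= 1, frame_index <= ncol(sgram$mag))
  sub <- sgram
  sub$mag <- sgram$mag[, frame_index, drop = FALSE]
  tonality_frames(sub, band)[1]
}

#' Extract a peak-frequency contour from a detection box
#'
#' For every frame inside the box, finds the frequency at maximum amplitude
#' restricted to the box's frequency band (ties broken towards the lowest
#' bin), then cleans the contour by removing non-tonal frames: frames whose
#' in-band tonality falls below `tonality_floor` are dropped. An empty contour
#' (zero rows) is returned when every frame is removed.
#'
#' @param sgram A `usv_spectrogram`.
#' @param box A one-row data frame (or list) with `t_start`, `t_end`, `f_low`,
#'   `f_high` -- a detection box or ground-truth annotation.
#' @param tonality_floor Frames below this tonality are discarded.
#' @return A `usv_contour` tibble with columns `time`, `peak_freq`,
#'   `peak_amp`, `tonality`; attributes `hop` and `bin_width`.
#' @export
extract_contour <- function(sgram, box, tonality_floor = 0.3) {
  stopifnot(inherits(sgram, "usv_spectrogram"))
  ft <- sgram$frame_times
  fi <- which(ft >= box$t_start & ft <= box$t_end)
  if (!length(fi) || box$f_low >= max(sgram$bin_freqs) ||
      box$f_high <= min(sgram$bin_freqs)) {
    stop("box does not intersect the spectrogram extent")
  }
  bi <- band_bins(sgram, c(box$f_low, box$f_high))
  m <- sgram$mag[bi, fi, drop = FALSE]
  peak_idx <- apply(m, 2, which.max)          # which.max: lowest bin on ties
  peak_amp <- m[cbind(peak_idx, seq_along(fi))]
  # Tonality needs spectral context: over a band of only a few bins even a
  # pure tone looks "flat". Widen the tonality band to at least 6 kHz around
  # the box (the peak search above stays restricted to the box band).
  tband <- c(box$f_low, box$f_high)
  short_by <- 6000 - diff(tband)
  if (short_by > 0) tband <- tband + c(-1, 1) * short_by / 2
  tband[1] <- max(tband[1], sgram$bin_freqs[1])
  tband[2] <- min(tband[2], max(sgram$bin_freqs))
  ton <- tonality_frames(
    structure(list(mag = sgram$mag[, fi, drop = FALSE],
                   bin_freqs = sgram$bin_freqs), class = "usv_spectrogram"),
    tband
  )
  # clean the contour: non-tonal frames go, and so do frames far below the
  # contour peak (box edges widened by detection smoothing contain bed noise
  # whose peak picks would otherwise contaminate the start/end measurements)
  keep <- ton >= tonality_floor & peak_amp > 0 &
    peak_amp >= max(peak_amp) * 10^(-25 / 20)
  out <- tibble::tibble(
    time = ft[fi][keep],
    peak_freq = sgram$bin_freqs[bi][peak_idx][keep],
    peak_amp = peak_amp[keep],
    tonality = ton[keep]
  )
  attr(out, "hop") <- sgram$hop
  attr(out, "bin_width") <- sgram$bin_freqs[2] - sgram$bin_freqs[1]
  class(out) <- c("usv_contour", class(out))
  out
}

#' Acoustic features of a contour
#'
#' Condenses a peak-frequency contour into the temporal, spectral and
#' tonality-related parameters used by the noise classifier, the call-type
#' classifier and the clustering stage: duration; mean/min/max/start/end peak
#' frequency; bandwidth (max - min); contour slope (ordinary least squares of
#' peak frequency on time, Hz/s); sinuosity (contour path length over
#' straight-line length in frame/bin units, >= 1); mean tonality; and a
#' syllable-count estimate from amplitude gaps (runs separated by frame drops
#' or by amplitude falling 25 dB below the contour peak).
#'
#' A single-frame contour has `duration = hop`, `slope = 0`, `sinuosity = 1`.
#'
#' @param contour A `usv_contour` from [extract_contour()]; must be non-empty.
#' @return A one-row tibble of features.
#' @export
extract_features <- function(contour) {
  stopifnot(inherits(contour, "usv_contour"))
  if (nrow(contour) == 0L) stop("cannot extract features from an empty contour")
  hop <- attr(contour, "hop")
  bw <- attr(contour, "bin_width")
  t <- contour$time
  f <- contour$peak_freq
  n <- nrow(contour)
  if (n == 1L) {
    slope <- 0
    sinuosity <- 1
    duration <- hop
  } else {
    duration <- diff(range(t)) + hop
    slope <- stats::cov(t, f) / stats::var(t)
    dt <- diff(t) / hop
    df <- diff(f) / bw
    path <- sum(sqrt(dt^2 + df^2))
    straight <- sqrt(((t[n] - t[1]) / hop)^2 + ((f[n] - f[1]) / bw)^2)
    sinuosity <- if (straight > 0) max(1, path / straight) else max(1, path)
  }
  # syllable estimate: contiguous loud runs
  loud <- contour$peak_amp >= max(contour$peak_amp) * 10^(-25 / 20)
  gap_break <- c(FALSE, diff(t) > 2.5 * hop)
  run_id <- cumsum(gap_break | c(FALSE, diff(loud) != 0))
  n_syl <- length(unique(run_id[loud]))
  tibble::tibble(
    duration = duration,
    pf_mean = mean(f), pf_min = min(f), pf_max = max(f),
    pf_start = f[1], pf_end = f[n],
    bandwidth = max(f) - min(f),
    slope = slope, sinuosity = sinuosity,
    tonality_mean = mean(contour$tonality),
    n_syllables = as.double(max(1L, n_syl))
  )
}

#' Feature table for a set of boxes
#'
#' Convenience wrapper running [extract_contour()] + [extract_features()] for
#' every box of a detection or annotation table against one spectrogram.
#' Boxes whose contour comes back empty (nothing tonal inside the box) yield
#' `NA` features; downstream the noise classifier treats an untrackable
#' contour as noise.
#'
#' @param sgram A `usv_spectrogram`.
#' @param boxes A tibble of boxes with an id column (`detection_id` or
#'   `annotation_id`) and `t_start`/`t_end`/`f_low`/`f_high`.
#' @param tonality_floor Passed to [extract_contour()].
#' @return A tibble: the id column plus one feature row per box.
#' @export
extract_features_table <- function(sgram, boxes, tonality_floor = 0.3) {
  id_col <- intersect(c("detection_id", "annotation_id"), names(boxes))[1]
  if (is.na(id_col)) stop("boxes need a detection_id or annotation_id column")
  na_row <- tibble::as_tibble(as.list(stats::setNames(
    rep(NA_real_, length(FEATURE_COLS)), FEATURE_COLS
  )))
  rows <- purrr::map(seq_len(nrow(boxes)), function(i) {
    ctr <- tryCatch(
      extract_contour(sgram, boxes[i, ], tonality_floor = tonality_floor),
      error = function(e) NULL
    )
    if (is.null(ctr) || nrow(ctr) == 0L) na_row else extract_features(ctr)
  })
  out <- dplyr::bind_rows(rows)
  out[[id_col]] <- boxes[[id_col]]
  dplyr::relocate(out, dplyr::all_of(id_col))
}

FEATURE_COLS <- c(
  "duration", "pf_mean", "pf_min", "pf_max", "pf_start", "pf_end",
  "bandwidth", "slope", "sinuosity", "tonality_mean", "n_syllables"
)
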