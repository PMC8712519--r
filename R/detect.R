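#' Duration-stratified detector profile
#'
#' A deterministic spectrogram segmenter stands in for each of the three
#' duration-stratified call detectors: frames whose smoothed in-band energy
#' exceeds the noise floor by `energy_threshold_db` *and* whose full-band
#' tonality passes `min_tonality` are segmented into candidate boxes, gaps
#' shorter than one smoothing window are fused, and only segments inside the
#' profile's duration gate survive. The three nominal profiles mirror the
#' duration groups of the repertoire: `long` (long whistle, trill), `short`
#' (short whistle, tsak), `very_short` (zip).
#'
#' @param name Profile name: `"long"`, `"short"` or `"very_short"`.
#' @param min_duration,max_duration Duration gate in seconds.
#' @param smoothing_window Energy smoothing window in seconds (also the gap
#'   fusion span).
#' @param energy_threshold_db Threshold above the per-file noise floor
#'   (median in-band frame energy), in dB.
#' @param band Analysis band in Hz.
#' @param min_tonality Frames below this full-band tonality are not
#'   segmentable. The default is deliberately permissive so that loud
#'   band-limited noise transients *are* detected (they are what the noise
#'   classifier is for) while the flat separator noise is not.
#' @return A `detector_profile` object.
#' @export
detector_profile <- function(name = c("long", "short", "very_short"),
                             min_duration, max_duration,
                             smoothing_window,
                             energy_threshold_db = 8,
                             band = USV_BAND,
                             min_tonality = 0.35) {
  name <- match.arg(name)
  stopifnot(min_duration < max_duration, smoothing_window > 0)
  structure(
    list(
      name = name, min_duration = min_duration, max_duration = max_duration,
      smoothing_window = smoothing_window,
      energy_threshold_db = energy_threshold_db,
      band = band, min_tonality = min_tonality
    ),
    class = "detector_profile"
  )
}

#' Default detector profiles
#'
#' Duration gates: long 0.15-3 s, short 0.02-0.2 s, very short 4-30 ms.
#' Smoothing windows shrink with the target duration so that trill syllable
#' gaps are fused by the long profile but series intercall intervals are not.
#'
#' @return Named list of three [detector_profile] objects.
#' @export
default_profiles <- function() {
  list(
    long = detector_profile("long", 0.15, 3.0, smoothing_window = 0.04),
    short = detector_profile("short", 0.02, 0.2, smoothing_window = 0.008),
    very_short = detector_profile("very_short", 0.004, 0.03,
                                  smoothing_window = 0.003)
  )
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

empty_detections <- function() {
  tibble::tibble(
    detection_id = character(), t_start = double(), t_end = double(),
    f_low = double(), f_high = double(), score = double(),
    source_detector = character(), label = NA_character_[0],
    status = character()
  )
}

#' Detect call candidates with one profile
#'
#' @param sgram A `usv_spectrogram` covering the profile's band.
#' @param profile A [detector_profile].
#' @return A detection tibble sorted by onset: `detection_id`, box
#'   coordinates, `score` (mean segment tonality), `source_detector`, `label`
#'   (`NA` until classification) and `status = "raw"`. An empty tibble is a
#'   valid result.
#' @export
detect_calls <- function(sgram, profile) {
  stopifnot(inherits(sgram, "usv_spectrogram"), inherits(profile, "detector_profile"))
  bi <- band_bins(sgram, profile$band)
  p <- sgram$mag[bi, , drop = FALSE]^2
  energy <- colSums(p)
  floor_e <- median(energy)
  thr <- floor_e * 10^(profile$energy_threshold_db / 10)
  w <- max(1L, round(profile$smoothing_window / sgram$hop))
  e_s <- moving_average(energy, w)
  ton <- tonality_frames(sgram, profile$band)
  active <- e_s >= thr & ton >= profile$min_tonality
  segs <- active_segments(active, fuse_below = w)
  if (!nrow(segs)) return(empty_detections())
  hop <- sgram$hop
  ft <- sgram$frame_times
  out <- purrr::pmap(segs, function(from, to) {
    t_start <- ft[from] - hop / 2
    t_end <- ft[to] + hop / 2
    dur <- t_end - t_start
    if (dur < profile$min_duration || dur > profile$max_duration) return(NULL)
    msub <- rowMeans(p[, from:to, drop = FALSE])
    keep <- which(msub >= max(msub) * 10^(-20 / 10))
    bwidth <- sgram$bin_freqs[2] - sgram$bin_freqs[1]
    f_lo <- max(profile$band[1], sgram$bin_freqs[bi][min(keep)] - bwidth / 2)
    f_hi <- min(profile$band[2], sgram$bin_freqs[bi][max(keep)] + bwidth / 2)
    tibble::tibble(
      t_start = t_start, t_end = t_end, f_low = f_lo, f_high = f_hi,
      score = mean(ton[from:to]), source_detector = profile$name,
      label = NA_character_, status = "raw"
    )
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) return(empty_detections())
  out <- dplyr::arrange(out, .data$t_start)
  out$detection_id <- sprintf("%s_%03d", profile$name, seq_len(nrow(out)))
  dplyr::relocate(out, "detection_id")
}

# rle-based segmentation with fusion of FALSE gaps shorter than `fuse_below`
# frames (gaps at the sequence edges are never fused).
active_segments <- function(active, fuse_below) {
  r <- rle(active)
  if (length(r$values) > 2L) {
    inner <- seq(2L, length(r$values) - 1L)
    fuse <- inner[!r$values[inner] & r$lengths[inner] < fuse_below]
    r$values[fuse] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(from = starts[r$values], to = ends[r$values])
}

#' Run all detector profiles simultaneously
#'
#' Concatenates the per-profile outputs with their `source_detector` tags.
#' Deliberately performs no deduplication: removing the doublet boxes that the
#' simultaneous profiles produce (e.g. trill syllables re-detected by the
#' short profile) is the post-filter's job, see [rds_filter()].
#'
#' @param sgram A `usv_spectrogram`.
#' @param profiles Named list of [detector_profile]s.
#' @return Detection tibble sorted by onset; size equals the sum of the
#'   single-profile output sizes.
#' @export
multi_detect <- function(sgram, profiles = default_profiles()) {
  out <- dplyr::bind_rows(lapply(profiles, function(p) detect_calls(sgram, p)))
  if (!nrow(out)) return(empty_detections())
  dplyr::arrange(out, .data$t_start, .data$detection_id)
}
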