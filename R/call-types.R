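#' Parametric description of a call type
#'
#' Describes one call type of the gray mouse lemur adult high-frequency
#' repertoire as a set of sampling ranges. All frequency content is constrained
#' to the 5-50 kHz analysis band. The exact per-type parameter tables of the
#' source archive are not public; the defaults in [default_repertoire()] are
#' this package's own reconstruction and every value is configurable.
#'
#' @param name Call type name, one of `long_whistle`, `trill`, `short_whistle`,
#'   `tsak`, `zip`.
#' @param duration_range For single-syllable contours, the call duration range
#'   in seconds; for `multi_syllable` contours, the per-syllable duration range.
#' @param f_start_range Fundamental start frequency range (Hz). For
#'   `sinusoidal_fm`/`multi_syllable` contours this is the carrier range.
#' @param sweep_range Downward frequency sweep extent range (Hz); the end
#'   frequency is `f_start - sweep` (negative sweep rises). Ignored for
#'   `sinusoidal_fm` contours.
#' @param sweep_skew Exponent applied to the uniform draw of the sweep: values
#'   > 1 skew the distribution towards shallow sweeps (used for the mostly-flat
#'   short whistle whose occasional steep variants grade into the zip).
#' @param contour_shape One of `flat`, `down_sweep`, `up_sweep`,
#'   `sinusoidal_fm`, `multi_syllable`.
#' @param n_syllable_range Range (inclusive) of syllable counts; > 1 only for
#'   the trill.
#' @param syllable_gap_range Inter-syllable silent gap range (s).
#' @param fm_depth_range Frequency-modulation depth range (Hz).
#' @param fm_rate_range Frequency-modulation rate range (Hz).
#' @param amplitude_envelope `"hann"` (smooth onset/offset, whistles and trill
#'   syllables) or `"trapezoid"` (sharp onset, tsak and zip).
#' @param amplitude_range Peak amplitude range on the full scale.
#' @param series_size 1, or 3 for the series-emitted types (tsak, short
#'   whistle).
#' @param intercall_interval_range Within-series intercall interval range (s);
#'   upper bound must be < 0.2 s.
#' @return A `call_type_spec` object (a validated list).
#' @seealso [default_repertoire()], [sister_species_variant()], [synth_call()]
#' @export
call_type_spec <- function(name,
                           duration_range,
                           f_start_range,
                           sweep_range = c(0, 0),
                           sweep_skew = 1,
                           contour_shape = c("flat", "down_sweep", "up_sweep",
                                             "sinusoidal_fm", "multi_syllable"),
                           n_syllable_range = c(1L, 1L),
                           syllable_gap_range = c(0, 0),
                           fm_depth_range = c(0, 0),
                           fm_rate_range = c(0, 0),
                           amplitude_envelope = c("hann", "trapezoid"),
                           amplitude_range = c(0.6, 0.8),
                           series_size = 1L,
                           intercall_interval_range = c(0.05, 0.15)) {
  contour_shape <- match.arg(contour_shape)
  amplitude_envelope <- match.arg(amplitude_envelope)
  name <- match.arg(name, CALL_TYPES)
  rng <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop("invalid range for ", what)
    }
    as.double(r)
  }
  duration_range <- rng(duration_range, "duration_range")
  f_start_range <- rng(f_start_range, "f_start_range")
  sweep_range <- rng(sweep_range, "sweep_range")
  stopifnot(duration_range[1] > 0)
  if (series_size != 1L && series_size != 3L) {
    stop("series_size must be 1, or 3 for series-emitted types")
  }
  if (series_size == 3L && intercall_interval_range[2] >= 0.2) {
    stop("intercall intervals within a series must stay below 0.2 s")
  }
  if (n_syllable_range[2] > 1L && name != "trill") {
    stop("multi-syllable structure is reserved for the trill")
  }
  # band confinement: start, end and FM excursion must stay inside 5-50 kHz
  f_lo <- f_start_range[1] - max(sweep_range[2], 0) - fm_depth_range[2]
  f_hi <- f_start_range[2] + max(-sweep_range[1], 0) + fm_depth_range[2]
  if (f_lo < USV_BAND[1] || f_hi > USV_BAND[2]) {
    stop("call frequency content must lie within 5-50 kHz")
  }
  structure(
    list(
      name = name, duration_range = duration_range,
      f_start_range = f_start_range, sweep_range = sweep_range,
      sweep_skew = sweep_skew, contour_shape = contour_shape,
      n_syllable_range = as.integer(n_syllable_range),
      syllable_gap_range = as.double(syllable_gap_range),
      fm_depth_range = as.double(fm_depth_range),
      fm_rate_range = as.double(fm_rate_range),
      amplitude_envelope = amplitude_envelope,
      amplitude_range = as.double(amplitude_range),
      series_size = as.integer(series_size),
      intercall_interval_range = as.double(intercall_interval_range)
    ),
    class = "call_type_spec"
  )
}

#' @export
print.call_type_spec <- function(x, ...) {
  cat(sprintf(
    "<call_type_spec %s: %s, %.0f-%.0f ms, f0 %.1f-%.1f kHz%s>\n",
    x$name, x$contour_shape,
    1000 * x$duration_range[1], 1000 * x$duration_range[2],
    x$f_start_range[1] / 1000, x$f_start_range[2] / 1000,
    if (x$series_size > 1L) sprintf(", series of %d", x$series_size) else ""
  ))
  invisible(x)
}

#' Default five-type repertoire
#'
#' The five high-frequency/ultrasonic call types of the adult gray mouse lemur
#' repertoire modelled by the synthesizer. Duration groups are chosen so the
#' three duration-stratified detector profiles are recoverable: long whistle
#' and trill are long calls (> 0.2 s), short whistle and tsak short calls
#' (15-90 ms, emitted as series of three), and the zip a very short (< 25 ms)
#' steep down-sweep. The short whistle's sweep distribution has a heavy shallow
#' side with a steep tail so that its shortest, steepest variants grade into
#' the zip, as the natural repertoire does.
#'
#' @return Named list of [call_type_spec] objects.
#' @export
default_repertoire <- function() {
  list(
    long_whistle = call_type_spec(
      "long_whistle", duration_range = c(0.2, 1.5),
      f_start_range = c(14000, 30000), contour_shape = "flat",
      fm_depth_range = c(0, 1000), fm_rate_range = c(1, 4),
      amplitude_envelope = "hann"
    ),
    trill = call_type_spec(
      "trill", duration_range = c(0.06, 0.15),       # per syllable
      f_start_range = c(16000, 30000), contour_shape = "multi_syllable",
      n_syllable_range = c(3L, 8L), syllable_gap_range = c(0.01, 0.03),
      fm_depth_range = c(3000, 8000), fm_rate_range = c(20, 60),
      amplitude_envelope = "hann"
    ),
    short_whistle = call_type_spec(
      "short_whistle", duration_range = c(0.012, 0.09),
      f_start_range = c(25000, 45000), sweep_range = c(0, 20000),
      sweep_skew = 2, contour_shape = "down_sweep",
      amplitude_envelope = "hann", series_size = 3L,
      intercall_interval_range = c(0.09, 0.18)
    ),
    tsak = call_type_spec(
      "tsak", duration_range = c(0.02, 0.08),
      f_start_range = c(22000, 32000), sweep_range = c(8000, 16000),
      contour_shape = "down_sweep", amplitude_envelope = "trapezoid",
      series_size = 3L, intercall_interval_range = c(0.09, 0.18)
    ),
    zip = call_type_spec(
      "zip", duration_range = c(0.010, 0.018),
      f_start_range = c(38000, 43000), sweep_range = c(15000, 22000),
      contour_shape = "down_sweep", amplitude_envelope = "hann"
    )
  )
}

#' Sister-species trill variant
#'
#' Returns a trill specification with the altered syllable structure of the
#' closely related sister species: two longer syllables separated by a wider
#' gap, so duration-based detectors tend to box the two syllables separately.
#' Only defined for the trill; idempotent.
#'
#' @param spec A trill [call_type_spec].
#' @return A modified trill [call_type_spec] with `n_syllable_range = c(2, 2)`.
#' @export
sister_species_variant <- function(spec) {
  stopifnot(inherits(spec, "call_type_spec"))
  if (spec$name != "trill") {
    stop("the sister-species contour variant is defined for the trill only")
  }
  spec$n_syllable_range <- c(2L, 2L)
  spec$duration_range <- c(0.15, 0.3)
  spec$syllable_gap_range <- c(0.05, 0.08)
  spec
}
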