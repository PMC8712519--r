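#' @title Synthetic call rendering
#' @description Internal renderers draw call parameters from a
#'   [call_type_spec] using the current RNG state and integrate the resulting
#'   instantaneous-frequency trajectory into a waveform. Public entry points
#'   seed the RNG explicitly so re-running with the same seed is byte-identical.
#' @name synth-internal
#' @keywords internal
NULL

runif1 <- function(r) if (r[1] == r[2]) r[1] else runif(1, r[1], r[2])

# Amplitude envelope on [0, 1]: hann (= sin^2) or trapezoid with 15% ramps.
call_envelope <- function(n, shape) {
  x <- seq(0, 1, length.out = n)
  if (shape == "hann") {
    sin(pi * x)^2
  } else {
    ramp <- 0.15
    pmin(1, pmin(x, 1 - x) / ramp)
  }
}

# Render one syllable: returns samples and per-sample instantaneous frequency.
render_syllable <- function(spec, sr) {
  dur <- runif1(spec$duration_range)
  n <- max(8L, round(dur * sr))
  tt <- (seq_len(n) - 0.5) / sr
  f0 <- runif1(spec$f_start_range)
  f <- switch(spec$contour_shape,
    flat = ,
    sinusoidal_fm = ,
    multi_syllable = {
      depth <- runif1(spec$fm_depth_range)
      rate <- runif1(spec$fm_rate_range)
      phase0 <- runif(1, 0, 2 * pi)
      f0 + depth * sin(2 * pi * rate * tt + phase0)
    },
    down_sweep = {
      sweep <- diff(spec$sweep_range) * runif(1)^spec$sweep_skew +
        spec$sweep_range[1]
      f_end <- max(f0 - sweep, USV_BAND[1] + 500)
      seq(f0, f_end, length.out = n)
    },
    up_sweep = {
      sweep <- runif1(spec$sweep_range)
      f_end <- min(f0 + sweep, USV_BAND[2] - 500)
      seq(f0, f_end, length.out = n)
    }
  )
  f <- pmin(pmax(f, USV_BAND[1]), USV_BAND[2])
  env <- call_envelope(n, spec$amplitude_envelope)
  phase <- 2 * pi * cumsum(f) / sr
  list(samples = env * sin(phase), freq = f, env = env)
}

# Render one call (1 syllable, or n gapped syllables for the trill).
# Uses the current RNG state. Returns samples plus the trajectory of active
# (voiced) samples, used by the annotation box and by parameter-recovery tests.
render_call <- function(spec, sr) {
  n_syl <- if (spec$n_syllable_range[2] > 1L) {
    choices <- seq(spec$n_syllable_range[1], spec$n_syllable_range[2])
    choices[sample.int(length(choices), 1L)]    # safe for length-1 ranges
  } else 1L
  amp <- runif1(spec$amplitude_range)
  parts <- vector("list", n_syl)
  gaps <- if (n_syl > 1L) {
    round(runif(n_syl - 1L, spec$syllable_gap_range[1],
                spec$syllable_gap_range[2]) * sr)
  } else integer(0)
  for (i in seq_len(n_syl)) parts[[i]] <- render_syllable(spec, sr)
  lens <- vapply(parts, function(p) length(p$samples), integer(1))
  total <- sum(lens) + sum(gaps)
  samples <- numeric(total)
  freq <- rep(NA_real_, total)
  env <- numeric(total)
  pos <- 0L
  for (i in seq_len(n_syl)) {
    idx <- pos + seq_len(lens[i])
    samples[idx] <- parts[[i]]$samples
    freq[idx] <- parts[[i]]$freq
    env[idx] <- parts[[i]]$env
    pos <- pos + lens[i] + if (i < n_syl) gaps[i] else 0L
  }
  samples <- amp * samples
  # annotation box: energy above -40 dB of the call peak
  active <- env >= 0.01
  t_act <- range(which(active))
  f_act <- range(freq[active], na.rm = TRUE)
  list(
    samples = samples,
    t_start = (t_act[1] - 1) / sr, t_end = t_act[2] / sr,
    f_low = max(USV_BAND[1], f_act[1] - 400),
    f_high = min(USV_BAND[2], f_act[2] + 400),
    freq = freq, n_syllables = n_syl, amp = amp
  )
}

new_annotation <- function(t_start, t_end, f_low, f_high, call_type,
                           series_id = NA_character_, scenario = "good",
                           overlaid_with = NA_character_) {
  tibble::tibble(
    annotation_id = NA_character_, t_start = t_start, t_end = t_end,
    f_low = f_low, f_high = f_high, call_type = call_type,
    series_id = series_id, scenario = scenario, overlaid_with = overlaid_with
  )
}

# Render one emission unit: a single call, or a series of `series_size` calls
# separated by intercall intervals < 200 ms. Returns samples + annotations
# (times relative to unit start).
render_unit <- function(spec, sr, scenario = "good", series_id = NA_character_) {
  k <- spec$series_size
  calls <- vector("list", k)
  icis <- if (k > 1L) {
    round(runif(k - 1L, spec$intercall_interval_range[1],
                spec$intercall_interval_range[2]) * sr)
  } else integer(0)
  for (i in seq_len(k)) calls[[i]] <- render_call(spec, sr)
  lens <- vapply(calls, function(cc) length(cc$samples), integer(1))
  total <- sum(lens) + sum(icis)
  samples <- numeric(total)
  anns <- vector("list", k)
  pos <- 0L
  for (i in seq_len(k)) {
    idx <- pos + seq_len(lens[i])
    samples[idx] <- calls[[i]]$samples
    t0 <- pos / sr
    anns[[i]] <- new_annotation(
      t0 + calls[[i]]$t_start, t0 + calls[[i]]$t_end,
      calls[[i]]$f_low, calls[[i]]$f_high, spec$name,
      series_id = series_id, scenario = scenario
    )
    pos <- pos + lens[i] + if (i < k) icis[i] else 0L
  }
  list(samples = samples, annotations = dplyr::bind_rows(anns))
}

#' Synthesize a single call
#'
#' Draws call parameters (duration, frequencies, modulation, amplitude) from
#' the ranges in `spec` under the given seed and integrates the resulting
#' instantaneous-frequency contour into a waveform. The annotation box tightly
#' encloses the energy above -40 dB of the call peak. Re-running with the same
#' spec and seed yields a byte-identical waveform.
#'
#' @param spec A [call_type_spec].
#' @param seed Integer seed controlling all random draws.
#' @param sample_rate Sampling rate in Hz; must be at least 100 kHz (twice the
#'   50 kHz band edge).
#' @return A list with elements `clip` ([usv_audio]) and `annotation` (a
#'   one-row annotation tibble). The generating instantaneous-frequency
#'   trajectory is attached as attribute `"trajectory"` (a tibble with `time`
#'   and `freq`, `NA` in syllable gaps) for measurement-validation use.
#' @examples
#' rep5 <- default_repertoire()
#' zz <- synth_call(rep5$zip, seed = 1, sample_rate = 192000)
#' zz$annotation
#' @export
synth_call <- function(spec, seed, sample_rate = 192000) {
  stopifnot(inherits(spec, "call_type_spec"))
  check_sample_rate(sample_rate)
  withr::with_seed(as.integer(seed), {
    cc <- render_call(spec, sample_rate)
    ann <- new_annotation(cc$t_start, cc$t_end, cc$f_low, cc$f_high, spec$name)
    ann$annotation_id <- "a001"
    traj <- tibble::tibble(
      time = (seq_along(cc$freq) - 0.5) / sample_rate, freq = cc$freq
    )
    out <- list(clip = usv_audio(cc$samples, sample_rate), annotation = ann)
    attr(out, "trajectory") <- traj
    out
  })
}

check_sample_rate <- function(sample_rate) {
  if (!is.numeric(sample_rate) || sample_rate < 2 * USV_BAND[2]) {
    stop(
      "`sample_rate` must be at least ", 2 * USV_BAND[2],
      " Hz (twice the 50 kHz analysis band edge)"
    )
  }
  invisible(TRUE)
}
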