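#' Scene specification
#'
#' Describes one synthetic recording to be rendered with exact ground truth:
#' either a *standardized* file (one call type, units separated by white-noise
#' separators, optionally degraded by a quality scenario) or an *experimental*
#' scene (mixed call types plus broadband noise events over a continuous noise
#' bed). The seed fully determines the rendered waveform and annotation table.
#'
#' The archive protocol this emulates inserted "3 s of white noise" separators
#' at a nominal 28 dB amplitude whose reference level is not stated; here the
#' separator/bed level is an explicit parameter, `noise_level_db` (dBFS RMS),
#' calibrated by default so good-quality calls sit at roughly 30 dB peak SNR.
#'
#' @param kind `"standardized"` or `"experimental"`.
#' @param scenario Recording-quality scenario: `"good"`, `"clipped"`,
#'   `"low_amplitude"` or `"overlaid"`.
#' @param call_types For standardized scenes a single call type name; for
#'   experimental scenes a named integer vector of unit counts per call type
#'   (a unit is one call, or one series of three for tsak/short whistle).
#' @param n_units Number of units in a standardized file.
#' @param noise_events Number of broadband noise transients (experimental
#'   scenes; scratching/digging proxy).
#' @param separator_duration Separator length in seconds (standardized).
#' @param noise_level_db Separator/bed white-noise level, dBFS RMS.
#' @param clip_level Saturation bound for the clipped scenario.
#' @param attenuation_db Gain applied in the low-amplitude scenario (dB).
#' @param sample_rate Sampling rate (Hz, >= 100 kHz).
#' @param duration Optional experimental scene length (s). If given, units are
#'   placed at random onsets with bounded retries; otherwise sequentially with
#'   random gaps.
#' @param repertoire Named list of [call_type_spec] objects.
#' @param seed Integer seed; fully determines the scene.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(kind = c("standardized", "experimental"),
                       scenario = c("good", "clipped", "low_amplitude",
                                    "overlaid"),
                       call_types, n_units = 10L, noise_events = 0L,
                       separator_duration = 3, noise_level_db = -33,
                       clip_level = 0.5, attenuation_db = -15,
                       sample_rate = 192000, duration = NULL,
                       repertoire = default_repertoire(), seed = 1L) {
  kind <- match.arg(kind)
  scenario <- match.arg(scenario)
  check_sample_rate(sample_rate)
  if (kind == "standardized") {
    if (length(call_types) != 1L || !call_types %in% names(repertoire)) {
      stop("a standardized scene contains exactly one known call type")
    }
    if (n_units < 1L) stop("a standardized scene needs at least one unit")
    if (scenario == "overlaid" && n_units < 2L) {
      stop("the overlaid scenario needs at least two units to overlay")
    }
  } else {
    if (length(call_types) < 1L || is.null(names(call_types)) ||
        !all(names(call_types) %in% names(repertoire))) {
      stop("experimental scenes need a named count per call type")
    }
  }
  structure(
    list(
      kind = kind, scenario = scenario, call_types = call_types,
      n_units = as.integer(n_units), noise_events = as.integer(noise_events),
      separator_duration = separator_duration,
      noise_level_db = noise_level_db, clip_level = clip_level,
      attenuation_db = attenuation_db, sample_rate = sample_rate,
      duration = duration, repertoire = repertoire, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

# scenario degradation applied to a unit's raw samples (before mixing)
degrade_unit <- function(samples, spec) {
  switch(spec$scenario,
    good = ,
    overlaid = samples,
    clipped = pmin(pmax(samples, -spec$clip_level), spec$clip_level),
    low_amplitude = samples * 10^(spec$attenuation_db / 20)
  )
}

# Broadband filtered-noise transient (scratching/digging proxy). The burst is
# band-limited to a few kHz around a random centre, which makes it look
# line-like to a full-band tonality measure -- exactly the kind of event the
# detector flags and the denoiser must learn to reject.
render_noise_event <- function(sr) {
  dur <- runif(1, 0.03, 0.15)
  n <- round(dur * sr)
  fc <- runif(1, 9000, 28000)
  hw <- runif(1, 1500, 4000)
  amp <- runif(1, 0.15, 0.35)
  bf <- signal::butter(4, c(fc - hw, fc + hw) / (sr / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x <- x / max(abs(x)) * amp * call_envelope(n, "trapezoid")
  list(
    samples = x,
    annotation = new_annotation(
      0, n / sr, max(USV_BAND[1], fc - hw - 500),
      min(USV_BAND[2], fc + hw + 500), "noise"
    )
  )
}

# Overlay unit B onto unit A at ~half of A's span; cross-link overlapping
# annotations through overlaid_with (ids are assigned after assembly, so link
# by row using temporary keys).
overlay_units <- function(a, b, sr) {
  off_s <- 0.5 * length(a$samples) / sr
  off <- round(off_s * sr)
  n <- max(length(a$samples), off + length(b$samples))
  samples <- numeric(n)
  samples[seq_along(a$samples)] <- a$samples
  idx <- off + seq_along(b$samples)
  samples[idx] <- samples[idx] + b$samples
  bann <- b$annotations
  bann$t_start <- bann$t_start + off_s
  bann$t_end <- bann$t_end + off_s
  ann <- dplyr::bind_rows(a$annotations, bann)
  ann$.key <- seq_len(nrow(ann))
  na <- nrow(a$annotations)
  for (i in seq_len(na)) {
    ovl <- pmin(ann$t_end[i], bann$t_end) - pmax(ann$t_start[i], bann$t_start)
    j <- which.max(ovl)
    if (length(j) && ovl[j] > 0) {
      ann$overlaid_with[i] <- as.character(na + j)
      if (is.na(ann$overlaid_with[na + j])) {
        ann$overlaid_with[na + j] <- as.character(i)
      }
    }
  }
  list(samples = samples, annotations = ann)
}

# Assemble segments into a file: [sep seg sep seg ... sep] over a continuous
# white-noise bed; returns clip + absolute-time annotations.
assemble_segments <- function(segments, spec) {
  sr <- spec$sample_rate
  sep_n <- round(spec$separator_duration * sr)
  seg_lens <- vapply(segments, function(s) length(s$samples), integer(1))
  total <- sum(seg_lens) + sep_n * (length(segments) + 1L)
  sigma <- 10^(spec$noise_level_db / 20)
  samples <- rnorm(total) * sigma
  anns <- vector("list", length(segments))
  pos <- sep_n
  for (i in seq_along(segments)) {
    idx <- pos + seq_len(seg_lens[i])
    samples[idx] <- samples[idx] + segments[[i]]$samples
    a <- segments[[i]]$annotations
    if (".key" %in% names(a)) {   # make overlay keys unique across segments
      a$.key <- paste0(i, "_", a$.key)
      linked <- !is.na(a$overlaid_with)
      a$overlaid_with[linked] <- paste0(i, "_", a$overlaid_with[linked])
    }
    a$t_start <- a$t_start + pos / sr
    a$t_end <- a$t_end + pos / sr
    anns[[i]] <- a
    pos <- pos + seg_lens[i] + sep_n
  }
  ann <- dplyr::bind_rows(anns)
  ann <- finalize_annotations(ann, spec$scenario)
  list(clip = usv_audio(samples, sr), annotations = ann)
}

# sort by onset, assign ids, remap overlaid_with keys to final ids
finalize_annotations <- function(ann, scenario) {
  if (!".key" %in% names(ann)) ann$.key <- NA_integer_
  ord <- order(ann$t_start)
  ann <- ann[ord, ]
  ann$annotation_id <- sprintf("a%03d", seq_len(nrow(ann)))
  key_map <- stats::setNames(ann$annotation_id, as.character(ann$.key))
  has_link <- !is.na(ann$overlaid_with)
  ann$overlaid_with[has_link] <- unname(key_map[ann$overlaid_with[has_link]])
  ann$scenario <- scenario
  ann$.key <- NULL
  ann
}

#' Build a standardized evaluation file
#'
#' Renders a single-call-type file in the archive's standardized layout:
#' alternating white-noise separators and call units (a unit is one call, or a
#' series of three calls with intercall intervals < 200 ms for tsak and short
#' whistle), over a continuous noise bed. Quality scenarios degrade each unit
#' before mixing: `clipped` hard-limits, `low_amplitude` attenuates, and
#' `overlaid` superimposes consecutive unit pairs at half-unit offset and
#' cross-links the overlapping annotations.
#'
#' @param spec A standardized [scene_spec()].
#' @return A list with `clip` ([usv_audio]) and `annotations` (tibble sorted by
#'   onset, absolute file times, half-open intervals).
#' @export
build_standardized_file <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$kind != "standardized") stop("spec$kind must be 'standardized'")
  ct <- spec$call_types
  cspec <- spec$repertoire[[ct]]
  sr <- spec$sample_rate
  withr::with_seed(spec$seed, {
    units <- vector("list", spec$n_units)
    for (i in seq_len(spec$n_units)) {
      sid <- if (cspec$series_size > 1L) sprintf("s%03d", i) else NA_character_
      u <- render_unit(cspec, sr, scenario = spec$scenario, series_id = sid)
      u$samples <- degrade_unit(u$samples, spec)
      units[[i]] <- u
    }
    segments <- if (spec$scenario == "overlaid") {
      pairs <- split(units, ceiling(seq_along(units) / 2))
      lapply(pairs, function(p) {
        if (length(p) == 2L) overlay_units(p[[1]], p[[2]], sr) else p[[1]]
      })
    } else {
      units
    }
    assemble_segments(segments, spec)
  })
}

#' Build an experimental (mixed) scene
#'
#' Renders a scene mimicking original experimental recordings: units of
#' several call types and broadband noise events placed over a continuous
#' noise bed. Without `duration`, segments are laid out sequentially with
#' random gaps (always non-overlapping); with `duration`, onsets are drawn
#' uniformly and re-drawn on collision, failing after bounded retries if the
#' requested density cannot be placed.
#'
#' @param spec An experimental [scene_spec()].
#' @return A list with `clip` and `annotations` (noise events are annotated
#'   with `call_type = "noise"`).
#' @export
build_experimental_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$kind != "experimental") stop("spec$kind must be 'experimental'")
  sr <- spec$sample_rate
  withr::with_seed(spec$seed, {
    units <- list()
    series_counter <- 0L
    for (ct in names(spec$call_types)) {
      cspec <- spec$repertoire[[ct]]
      for (i in seq_len(spec$call_types[[ct]])) {
        sid <- if (cspec$series_size > 1L) {
          series_counter <- series_counter + 1L
          sprintf("s%03d", series_counter)
        } else NA_character_
        u <- render_unit(cspec, sr, scenario = spec$scenario, series_id = sid)
        u$samples <- degrade_unit(u$samples, spec)
        units <- c(units, list(u))
      }
    }
    for (i in seq_len(spec$noise_events)) {
      ne <- render_noise_event(sr)
      units <- c(units, list(list(samples = ne$samples,
                                  annotations = ne$annotation)))
    }
    if (!length(units)) stop("experimental scene with no content")
    units <- units[sample(length(units))]
    if (is.null(spec$duration)) {
      sequential_scene(units, spec)
    } else {
      random_onset_scene(units, spec)
    }
  })
}

sequential_scene <- function(units, spec) {
  sr <- spec$sample_rate
  sigma <- 10^(spec$noise_level_db / 20)
  lens <- vapply(units, function(u) length(u$samples), integer(1))
  gaps <- round(runif(length(units) + 1L, 0.2, 0.6) * sr)
  total <- sum(lens) + sum(gaps)
  samples <- rnorm(total) * sigma
  anns <- vector("list", length(units))
  pos <- gaps[1]
  for (i in seq_along(units)) {
    idx <- pos + seq_len(lens[i])
    samples[idx] <- samples[idx] + units[[i]]$samples
    a <- units[[i]]$annotations
    a$t_start <- a$t_start + pos / sr
    a$t_end <- a$t_end + pos / sr
    anns[[i]] <- a
    pos <- pos + lens[i] + gaps[i + 1L]
  }
  ann <- finalize_annotations(dplyr::bind_rows(anns), spec$scenario)
  list(clip = usv_audio(samples, sr), annotations = ann)
}

random_onset_scene <- function(units, spec, max_retries = 200L) {
  sr <- spec$sample_rate
  sigma <- 10^(spec$noise_level_db / 20)
  total <- round(spec$duration * sr)
  lens <- vapply(units, function(u) length(u$samples), integer(1))
  if (sum(lens) > total) {
    stop("scene too dense: requested content exceeds the scene duration")
  }
  margin <- round(0.1 * sr)
  placed <- matrix(numeric(0), ncol = 2)
  starts <- integer(length(units))
  for (i in seq_along(units)) {
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      s <- sample.int(total - lens[i], 1L)
      if (!nrow(placed) ||
          all(s + lens[i] + margin < placed[, 1] |
              s > placed[, 2] + margin)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("scene too dense: could not place all units without overlap ",
           "after ", max_retries, " retries")
    }
    placed <- rbind(placed, c(s, s + lens[i]))
    starts[i] <- s
  }
  samples <- rnorm(total) * sigma
  anns <- vector("list", length(units))
  for (i in seq_along(units)) {
    idx <- starts[i] + seq_len(lens[i])
    samples[idx] <- samples[idx] + units[[i]]$samples
    a <- units[[i]]$annotations
    a$t_start <- a$t_start + starts[i] / sr
    a$t_end <- a$t_end + starts[i] / sr
    anns[[i]] <- a
  }
  ann <- finalize_annotations(dplyr::bind_rows(anns), spec$scenario)
  list(clip = usv_audio(samples, sr), annotations = ann)
}
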