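# Shared fixtures, memoized across test files within one run: the scenes and
# feature sets below are pure functions of their seeds, so caching only saves
# recomputation, never changes a result.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one standardized file + its spectrogram for a call type / scenario
fixture_scene <- function(call_type, scenario = "good", n_units = 4,
                          seed = 11) {
  key <- paste("scene", call_type, scenario, n_units, seed, sep = "_")
  cached(key, {
    sp <- scene_spec("standardized", scenario, call_types = call_type,
                     n_units = n_units, seed = seed)
    sc <- build_standardized_file(sp)
    sc$sgram <- compute_spectrogram(sc$clip)
    sc
  })
}

# labelled features: calls of the five types plus noise events
fixture_features <- function() {
  cached("features_mixed", {
    cfg <- pipeline_config(seed = 5)
    call_feature_set(
      c(long_whistle = 14, trill = 14, short_whistle = 26, tsak = 20,
        zip = 12),
      n_noise = 40, config = cfg, seed = 501
    )
  })
}

fixture_denoiser <- function() {
  cached("denoiser", {
    train_default_denoiser(
      pipeline_config(seed = 5, denoiser_n = c(call = 80, noise = 55))
    )
  })
}

fixture_classifier <- function() {
  cached("classifier", {
    fe <- fixture_features()
    fe <- fe[fe$label != "noise", ]
    suppressWarnings(train_classifier(fe, seed = 78))
  })
}

# a tiny experimental scene with noise events
fixture_experimental <- function(seed = 91) {
  key <- paste0("exp_", seed)
  cached(key, {
    sp <- scene_spec(
      "experimental", "good",
      call_types = c(long_whistle = 2, trill = 2, short_whistle = 2,
                     tsak = 2, zip = 2),
      noise_events = 5, seed = seed
    )
    sc <- build_experimental_scene(sp)
    sc$sgram <- compute_spectrogram(sc$clip)
    sc
  })
}

# hand-built detection/annotation tables for the evaluation toys
toy_box <- function(t_start, t_end, id = "d1", source = "long",
                    f_low = 10000, f_high = 30000) {
  tibble::tibble(
    detection_id = id, t_start = t_start, t_end = t_end,
    f_low = f_low, f_high = f_high, score = 0.9,
    source_detector = source, label = NA_character_, status = "raw"
  )
}

toy_ann <- function(t_start, t_end, id = "a1", call_type = "tsak",
                    series_id = NA_character_, overlaid_with = NA_character_) {
  tibble::tibble(
    annotation_id = id, t_start = t_start, t_end = t_end,
    f_low = 10000, f_high = 30000, call_type = call_type,
    series_id = series_id, scenario = "good", overlaid_with = overlaid_with
  )
}
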