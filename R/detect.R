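#' Detection ranges of the receiver per call type
#'
#' One-sided distances along the wall from the plot centre within which
#' the receiver registers each call type. Defaults are 26 m (purr), 30 m
#' (chat) and 16 m (chick beg); the chick range is shortest because begs
#' are quiet. Ranges are treated as one-sided and inclusive at the
#' boundary.
#'
#' @param adult_purr,adult_chat,chick_beg range in metres (> 0).
#' @return named numeric vector of class `detection_ranges`.
#' @export
detection_ranges <- function(adult_purr = 26, adult_chat = 30,
                             chick_beg = 16) {
  r <- c(adult_purr = adult_purr, adult_chat = adult_chat,
         chick_beg = chick_beg)
  if (any(r <= 0)) stop("detection ranges must be positive", call. = FALSE)
  structure(r, class = "detection_ranges")
}

#' Flag events inside the receiver's detection range
#'
#' Event-level (non-audio) fast path of the pipeline: an event is detected
#' iff its source lies within the one-sided detection range of its call
#' type, measured along the wall from the plot centre (boundary
#' inclusive).
#'
#' @param events event data frame with `call_type` and `position_m`.
#' @param ranges a [detection_ranges()].
#' @return `events` with a logical `detected` column.
#' @export
apply_detection_range <- function(events, ranges = detection_ranges()) {
  if (!all(events$call_type %in% names(ranges))) {
    stop("events contain call types with no configured range", call. = FALSE)
  }
  events$detected <- abs(events$position_m) <=
    unclass(ranges)[events$call_type]
  events
}

#' Estimate a detection range from playback tests
#'
#' Given playback positions on a 2 m grid along the wall (signed metres
#' from the plot centre) and whether each playback was audible in the
#' recording, returns the detection range as the mean over the two sides
#' of the furthest detected position (each side's maximum is rounded to
#' the grid first). If every tested position on both sides was detected,
#' the range equals the test extent and is flagged as censored.
#'
#' @param positions_m signed playback positions (m) on the test grid.
#' @param detected logical, playback audible in the recording.
#' @param grid_m test grid spacing (m).
#' @return list with `range_m`, `left_m`, `right_m` (per-side maxima, `NA`
#'   where a side was untested or had no detections) and `censored`.
#' @export
estimate_detection_range <- function(positions_m, detected, grid_m = 2) {
  stopifnot(length(positions_m) == length(detected))
  if (!any(detected)) {
    warning("no detections; returning range 0")
    return(list(range_m = 0, left_m = NA_real_, right_m = NA_real_,
                censored = FALSE))
  }
  side_max <- function(side) {
    pos <- abs(positions_m[side])
    det <- detected[side]
    if (!length(pos) || !any(det)) return(c(NA_real_, NA_real_))
    c(round(max(pos[det]) / grid_m) * grid_m, max(pos))
  }
  left <- side_max(positions_m < 0)
  right <- side_max(positions_m >= 0)
  sides <- c(left[1], right[1])
  extents <- c(left[2], right[2])
  range_m <- mean(sides, na.rm = TRUE)
  censored <- all(!is.na(sides)) && all(sides >= extents - grid_m / 2)
  list(range_m = range_m, left_m = left[1], right_m = right[1],
       censored = censored)
}

#' Distance attenuation and source level model
#'
#' Amplitude model used when rendering plot-night audio: a call of type
#' `t` emitted at distance `d` metres along the wall arrives with RMS
#' amplitude `10^((source_db[t] - k_db_per_m * d) / 20)` relative to unit
#' background noise at `noise_db = 0`. Source levels differ by call type
#' (chick begs are quiet) and, with the default detector settings, are
#' calibrated so detector recall collapses to zero just beyond the
#' default 26/30/16 m detection ranges.
#'
#' @param k_db_per_m propagation loss along the wall (dB per metre).
#' @param source_db named source levels (dB re unit-variance noise).
#' @return list of class `attenuation_model`.
#' @export
attenuation_model <- function(k_db_per_m = 0.5,
                              source_db = c(adult_purr = 20,
                                            adult_chat = 22.5,
                                            chick_beg = 15)) {
  structure(list(k_db_per_m = k_db_per_m, source_db = source_db),
            class = "attenuation_model")
}

#' RMS amplitude of a call arriving from a given distance
#' @param model an [attenuation_model()].
#' @param call_type call type name.
#' @param distance_m absolute distance along the wall (m).
#' @return linear RMS amplitude (monotonically decreasing in distance).
#' @export
arrival_amplitude <- function(model, call_type, distance_m) {
  10^((model$source_db[[call_type]] -
         model$k_db_per_m * abs(distance_m)) / 20)
}

#' Render a plot-night (or part of one) as audio
#'
#' Mixes synthesized calls for the given true events into Gaussian
#' background noise, each scaled by the attenuation model according to
#' its source position. Overlapping events are summed.
#'
#' @param events event data frame (`call_type`, `start_s`, `duration_s`,
#'   `position_m`); may be empty.
#' @param noise_db background noise RMS in dBFS (dB re full scale). Call
#'   source levels are expressed relative to the noise floor, so the
#'   overall level only sets headroom: the default -30 dBFS keeps
#'   rendered audio safely inside the PCM-16 range of [write_wav()].
#' @param attenuation an [attenuation_model()].
#' @param duration_s clip length in seconds; defaults to covering the
#'   last event (plus a second), or 10 s for an empty event set.
#' @param specs [call_type_specs()] used for synthesis.
#' @param sample_rate Hz.
#' @param seed integer seed (noise and per-call synthesis).
#' @return an [audio_clip()].
#' @export
render_plot_night <- function(events, noise_db = -30,
                              attenuation = attenuation_model(),
                              duration_s = NULL,
                              specs = call_type_specs(),
                              sample_rate = 16000, seed = NULL) {
  if (is.null(duration_s)) {
    duration_s <- if (nrow(events)) {
      ceiling(max(events$start_s + events$duration_s)) + 1
    } else 10
  }
  n <- round(duration_s * sample_rate)
  with_seed(seed, {
    x <- rnorm(n, sd = 10^(noise_db / 20))
    for (i in seq_len(NROW(events))) {
      ev <- events[i, ]
      call <- synthesize_call(specs[[ev$call_type]],
                              duration_s = ev$duration_s,
                              sample_rate = sample_rate)
      amp <- 10^(noise_db / 20) *
        arrival_amplitude(attenuation, ev$call_type, ev$position_m)
      i0 <- round(ev$start_s * sample_rate)
      idx <- (i0 + 1):min(i0 + length(call$samples), n)
      x[idx] <- x[idx] + amp * call$samples[seq_along(idx)]
    }
    audio_clip(x, sample_rate)
  })
}

#' Detector configuration
#'
#' Tuning parameters of the rule-based spectrogram detector. Syllables
#' are segmented on the broadband energy envelope with hysteresis
#' thresholds relative to the clip's estimated noise floor (its median
#' envelope); syllables closer than `merge_gap_s` form one call event.
#' Events are classified from band energy ratios and syllable structure.
#'
#' @param frame_s envelope frame length (s).
#' @param on_db,off_db hysteresis thresholds above the noise floor (dB):
#'   a syllable opens above `on_db` and closes below `off_db`.
#' @param merge_gap_s maximum silent gap within one call event (s);
#'   defaults just above the longest chat inter-syllable gap.
#' @param min_syllable_s minimum syllable duration (s).
#' @param min_event_s minimum total voiced duration of an event (s).
#' @param purr_gap_max_s gap below which a 2-syllable low-band event is a
#'   purr rather than a chat.
#' @param chick_band_frac minimum fraction of band energy in the
#'   chick-exclusive 2.6--4 kHz band (vs the purr-exclusive 0.3--2.5 kHz
#'   band) for a beg classification.
#' @param chunk_s processing chunk length (s); long clips are processed
#'   in chunks with overlap so a full night never resides in memory.
#' @param resample if `TRUE`, non-16 kHz input is linearly resampled to
#'   16 kHz; if `FALSE` (default) it is an error.
#' @return list of class `detector_control`.
#' @export
detector_control <- function(frame_s = 0.008, on_db = 10, off_db = 6,
                             merge_gap_s = 0.35, min_syllable_s = 0.04,
                             min_event_s = 0.1, purr_gap_max_s = 0.075,
                             chick_band_frac = 0.7, chunk_s = 60,
                             resample = FALSE) {
  structure(list(frame_s = frame_s, on_db = on_db, off_db = off_db,
                 merge_gap_s = merge_gap_s, min_syllable_s = min_syllable_s,
                 min_event_s = min_event_s, purr_gap_max_s = purr_gap_max_s,
                 chick_band_frac = chick_band_frac, chunk_s = chunk_s,
                 resample = resample),
            class = "detector_control")
}

#' Detect and classify calls in audio
#'
#' The deterministic stand-in for a trained call classifier, with the
#' same output contract: the seconds of each target call type present in
#' the audio. Syllables are segmented on the 0.2--6 kHz energy envelope
#' (hysteresis thresholds over the noise floor), grouped into events, and
#' classified: events whose energy sits in the chick band (2.6--4 kHz
#' rather than 0.3--2.5 kHz) are chick begs; remaining events with three
#' or more syllables or gaps longer than `purr_gap_max_s` are chats;
#' the rest are purrs. Per-type call seconds sum the voiced durations of
#' classified events. Deterministic for fixed audio and configuration.
#'
#' @param audio an [audio_clip()]; must be 16 kHz unless
#'   `control$resample` is `TRUE`.
#' @param specs [call_type_specs()].
#' @param control a [detector_control()].
#' @return list of class `call_detections`: `events` (data frame with
#'   `call_type`, `start_s`, `duration_s`, `n_syllables`) and `seconds`
#'   (named per-type totals).
#' @export
detect_calls <- function(audio, specs = call_type_specs(),
                         control = detector_control()) {
  stopifnot(inherits(audio, "audio_clip"))
  if (audio$sample_rate != 16000) {
    if (!control$resample) {
      stop("detector expects 16 kHz audio (got ", audio$sample_rate,
           " Hz); set detector_control(resample = TRUE) to resample",
           call. = FALSE)
    }
    n_new <- round(length(audio$samples) * 16000 / audio$sample_rate)
    audio <- audio_clip(approx(seq_along(audio$samples), audio$samples,
                               n = n_new)$y, 16000)
  }
  total_s <- clip_duration(audio)
  chunk_n <- round(control$chunk_s * audio$sample_rate)
  overlap_n <- round(3 * audio$sample_rate)
  events <- list()
  t0 <- 0L
  while (t0 < length(audio$samples)) {
    idx <- (t0 + 1):min(t0 + chunk_n + overlap_n, length(audio$samples))
    ev <- detect_calls_chunk(audio$samples[idx], audio$sample_rate,
                             specs, control)
    if (nrow(ev)) {
      ev$start_s <- ev$start_s + t0 / audio$sample_rate
      # keep only events starting in the chunk's canonical span; events in
      # the overlap belong to the next chunk
      ev <- ev[ev$start_s < (t0 + chunk_n) / audio$sample_rate, , drop = FALSE]
      events[[length(events) + 1]] <- ev
    }
    t0 <- t0 + chunk_n
  }
  events <- if (length(events)) {
    do.call(rbind, c(events, make.row.names = FALSE))
  } else {
    data.frame(call_type = character(), start_s = numeric(),
               duration_s = numeric(), n_syllables = integer(),
               stringsAsFactors = FALSE)
  }
  seconds <- setNames(numeric(length(specs)), names(specs))
  if (nrow(events)) {
    agg <- tapply(events$duration_s, events$call_type, sum)
    seconds[names(agg)] <- agg
  }
  seconds <- pmin(seconds, total_s)
  structure(list(events = events, seconds = seconds,
                 clip_duration_s = total_s),
            class = "call_detections")
}

#' @export
print.call_detections <- function(x, ...) {
  cat(sprintf("call detections over %.1f s of audio:\n", x$clip_duration_s))
  for (ty in names(x$seconds)) {
    cat(sprintf("  %-10s %4d events, %7.2f s\n", ty,
                sum(x$events$call_type == ty), x$seconds[[ty]]))
  }
  invisible(x)
}

detect_calls_chunk <- function(x, sr, specs, control) {
  frame_n <- round(control$frame_s * sr)
  env_broad <- frame_rms(band_filter(x, sr, 200, 6000), frame_n)
  env_low <- frame_rms(band_filter(x, sr, 300, 2500), frame_n)
  env_chick <- frame_rms(band_filter(x, sr, 2600, 4000), frame_n)
  floor_broad <- median(env_broad)
  on_thr <- floor_broad * 10^(control$on_db / 20)
  off_thr <- floor_broad * 10^(control$off_db / 20)
  syl <- segment_hysteresis(env_broad, on_thr, off_thr)
  if (!nrow(syl)) {
    return(data.frame(call_type = character(), start_s = numeric(),
                      duration_s = numeric(), n_syllables = integer(),
                      stringsAsFactors = FALSE))
  }
  syl$dur <- (syl$end - syl$start + 1) * control$frame_s
  syl <- syl[syl$dur >= control$min_syllable_s, , drop = FALSE]
  if (!nrow(syl)) {
    return(data.frame(call_type = character(), start_s = numeric(),
                      duration_s = numeric(), n_syllables = integer(),
                      stringsAsFactors = FALSE))
  }
  gap_before <- c(Inf, (syl$start[-1] - syl$end[-nrow(syl)] - 1) *
                    control$frame_s)
  event_id <- cumsum(gap_before > control$merge_gap_s)
  out <- lapply(split(seq_len(nrow(syl)), event_id), function(ii) {
    s <- syl[ii, , drop = FALSE]
    voiced <- sum(s$dur)
    if (voiced < control$min_event_s) return(NULL)
    frames <- unlist(lapply(ii, function(j) syl$start[j]:syl$end[j]))
    # noise-corrected band energies over voiced frames
    e_low <- max(mean(env_low[frames]^2) - median(env_low)^2, 0)
    e_chick <- max(mean(env_chick[frames]^2) - median(env_chick)^2, 0)
    chick_frac <- if (e_low + e_chick > 0) e_chick / (e_low + e_chick) else 0
    gaps <- if (nrow(s) > 1) {
      (s$start[-1] - s$end[-nrow(s)] - 1) * control$frame_s
    } else numeric(0)
    type <- if (chick_frac >= control$chick_band_frac) {
      "chick_beg"
    } else if (nrow(s) >= 3 ||
               (length(gaps) && max(gaps) > control$purr_gap_max_s)) {
      "adult_chat"
    } else {
      "adult_purr"
    }
    data.frame(call_type = type,
               start_s = (s$start[1] - 1) * control$frame_s,
               duration_s = voiced,
               n_syllables = nrow(s),
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    data.frame(call_type = character(), start_s = numeric(),
               duration_s = numeric(), n_syllables = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(out, make.row.names = FALSE))
  }
}

frame_rms <- function(x, frame_n) {
  n_frames <- floor(length(x) / frame_n)
  if (n_frames < 1) return(sqrt(mean(x^2)))
  m <- matrix(x[seq_len(n_frames * frame_n)], nrow = frame_n)
  sqrt(colMeans(m^2))
}

# hysteresis segmentation: open above on_thr, close below off_thr
segment_hysteresis <- function(env, on_thr, off_thr) {
  starts <- integer(0); ends <- integer(0)
  open <- FALSE; s <- 0L
  for (i in seq_along(env)) {
    if (!open && env[i] > on_thr) {
      open <- TRUE; s <- i
    } else if (open && env[i] < off_thr) {
      open <- FALSE
      starts <- c(starts, s); ends <- c(ends, i - 1L)
    }
  }
  if (open) { starts <- c(starts, s); ends <- c(ends, length(env)) }
  data.frame(start = starts, end = ends)
}
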