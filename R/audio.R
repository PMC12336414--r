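#' Acoustic parameters of the three storm petrel call types
#'
#' Default frequency bands, duration ranges, syllable counts and
#' inter-syllable gaps for the adult purr (territorial males, 0.3--3 kHz,
#' 1--2 s, 2 syllables, gap < 0.05 s), adult chat (both sexes, 0.2--6 kHz,
#' 0.8--1.5 s, 3 syllables, gap 0.1--0.3 s) and chick beg (2.6--4 kHz,
#' 0.2--0.5 s, single syllable) calls.
#'
#' @param adult_purr,adult_chat,chick_beg [call_type_spec()] objects.
#' @return a named list of call type specs, class `call_type_specs`.
#' @export
call_type_specs <- function(
    adult_purr = call_type_spec("adult_purr", freq_lo = 0.3, freq_hi = 3,
                                dur_lo = 1, dur_hi = 2, n_syllables = 2,
                                gap_lo = 0.01, gap_hi = 0.05),
    adult_chat = call_type_spec("adult_chat", freq_lo = 0.2, freq_hi = 6,
                                dur_lo = 0.8, dur_hi = 1.5, n_syllables = 3,
                                gap_lo = 0.1, gap_hi = 0.3),
    chick_beg = call_type_spec("chick_beg", freq_lo = 2.6, freq_hi = 4,
                               dur_lo = 0.2, dur_hi = 0.5, n_syllables = 1)) {
  structure(list(adult_purr = adult_purr, adult_chat = adult_chat,
                 chick_beg = chick_beg),
            class = "call_type_specs")
}

#' One call type's acoustic parameters
#'
#' @param call_type name of the call type.
#' @param freq_lo,freq_hi frequency band (kHz); must satisfy
#'   `freq_lo < freq_hi` and `freq_hi` at most the Nyquist frequency of
#'   the 16 kHz recording contract (8 kHz).
#' @param dur_lo,dur_hi total voiced duration range (s).
#' @param n_syllables syllable count (>= 1).
#' @param gap_lo,gap_hi inter-syllable gap range (s); required iff
#'   `n_syllables > 1`.
#' @return a list of class `call_type_spec`.
#' @export
call_type_spec <- function(call_type, freq_lo, freq_hi, dur_lo, dur_hi,
                           n_syllables, gap_lo = NULL, gap_hi = NULL) {
  if (!(freq_lo < freq_hi && freq_hi <= 8)) {
    stop("need freq_lo < freq_hi <= 8 kHz (Nyquist of 16 kHz audio)",
         call. = FALSE)
  }
  if (!(dur_lo < dur_hi) || dur_lo <= 0) {
    stop("need 0 < dur_lo < dur_hi", call. = FALSE)
  }
  if (n_syllables < 1) stop("`n_syllables` must be >= 1", call. = FALSE)
  has_gap <- !is.null(gap_lo) && !is.null(gap_hi)
  if (n_syllables == 1 && has_gap) {
    stop("single-syllable calls take no inter-syllable gap", call. = FALSE)
  }
  if (n_syllables > 1 && !has_gap) {
    stop("multi-syllable calls need gap_lo and gap_hi", call. = FALSE)
  }
  if (has_gap && !(0 < gap_lo && gap_lo <= gap_hi)) {
    stop("need 0 < gap_lo <= gap_hi", call. = FALSE)
  }
  structure(list(call_type = call_type, freq_lo = freq_lo, freq_hi = freq_hi,
                 dur_lo = dur_lo, dur_hi = dur_hi,
                 n_syllables = as.integer(n_syllables),
                 gap_lo = gap_lo, gap_hi = gap_hi),
            class = "call_type_spec")
}

#' Audio clip container
#'
#' @param samples numeric vector of finite amplitudes.
#' @param sample_rate sampling rate in Hz; the recording contract is
#'   16 kHz mono.
#' @return a list of class `audio_clip` with elements `samples`,
#'   `sample_rate`.
#' @export
audio_clip <- function(samples, sample_rate = 16000) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("non-finite amplitudes", call. = FALSE)
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("audio_clip: %.3f s at %d Hz (rms %.4g)\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip an [audio_clip()].
#' @return seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Synthesize a call
#'
#' Renders one call as band-limited noise bursts: `n_syllables` syllables
#' whose total voiced duration is drawn from the spec's duration range,
#' separated by gaps from the gap range, with energy confined to the
#' spec's frequency band and cosine on/off ramps to avoid clicks. Voiced
#' samples are normalised to unit RMS.
#'
#' @param spec a [call_type_spec()].
#' @param seed integer seed (`NULL` = current RNG stream).
#' @param sample_rate Hz.
#' @param duration_s force the total voiced duration (s) instead of
#'   drawing it from the spec's range (used when rendering events with
#'   known durations).
#' @return an [audio_clip()] with attributes `"syllables"` (data frame of
#'   syllable start/duration in seconds) and `"voiced_s"` (total voiced
#'   duration).
#' @export
synthesize_call <- function(spec, seed = NULL, sample_rate = 16000,
                            duration_s = NULL) {
  stopifnot(inherits(spec, "call_type_spec"))
  with_seed(seed, {
    total <- duration_s %||% runif(1, spec$dur_lo, spec$dur_hi)
    w <- runif(spec$n_syllables, 0.8, 1.2)
    syl_dur <- total * w / sum(w)
    gaps <- if (spec$n_syllables > 1) {
      runif(spec$n_syllables - 1, spec$gap_lo, spec$gap_hi)
    } else numeric(0)
    starts <- cumsum(c(0, syl_dur[-spec$n_syllables] + gaps))
    n_total <- ceiling((starts[spec$n_syllables] +
                          syl_dur[spec$n_syllables]) * sample_rate)
    x <- numeric(n_total)
    for (i in seq_len(spec$n_syllables)) {
      n <- max(round(syl_dur[i] * sample_rate), 8)
      burst <- band_noise(n, sample_rate, spec$freq_lo * 1000,
                          spec$freq_hi * 1000)
      burst <- burst * cosine_ramp(n, min(0.005 * sample_rate, n %/% 4))
      i0 <- round(starts[i] * sample_rate)
      x[(i0 + 1):(i0 + n)] <- x[(i0 + 1):(i0 + n)] + burst
    }
    rms <- sqrt(sum(x^2) / (total * sample_rate))
    clip <- audio_clip(x / rms, sample_rate)
    attr(clip, "syllables") <- data.frame(start_s = starts,
                                          duration_s = syl_dur)
    attr(clip, "voiced_s") <- total
    clip
  })
}

# white noise restricted to [lo_hz, hi_hz] via FFT masking
band_noise <- function(n, sample_rate, lo_hz, hi_hz) {
  x <- rnorm(n)
  band_filter(x, sample_rate, lo_hz, hi_hz)
}

# zero out spectral content outside [lo_hz, hi_hz] (two-sided mask)
band_filter <- function(x, sample_rate, lo_hz, hi_hz) {
  n <- length(x)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * sample_rate / n
  freqs <- pmin(freqs, sample_rate - freqs)  # fold to [0, Nyquist]
  X[freqs < lo_hz | freqs > hi_hz] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

cosine_ramp <- function(n, ramp_n) {
  env <- rep(1, n)
  ramp_n <- max(1, min(ramp_n, n %/% 2))
  up <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  env[seq_len(ramp_n)] <- up
  env[n + 1 - seq_len(ramp_n)] <- up
  env
}

#' Spectral centroid of a clip
#' @param clip an [audio_clip()].
#' @return centroid frequency in kHz.
#' @export
spectral_centroid <- function(clip) {
  n <- length(clip$samples)
  p <- Mod(fft(clip$samples))^2
  half <- seq_len(n %/% 2)
  freqs <- (half - 1) * clip$sample_rate / n
  sum(freqs * p[half]) / sum(p[half]) / 1000
}

#' Read a mono PCM-16 WAV file
#'
#' Minimal RIFF/WAVE reader for the package's own 16 kHz mono PCM-16
#' recording contract (no installed package provides WAV input).
#'
#' @param path file path.
#' @return an [audio_clip()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1) stop("only PCM WAV supported", call. = FALSE)
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (bits != 16) stop("only 16-bit PCM supported", call. = FALSE)
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(samples)) stop("no data chunk in WAV", call. = FALSE)
  if (n_channels != 1) stop("only mono WAV supported", call. = FALSE)
  audio_clip(samples / 32767, sample_rate)
}

#' Write a mono PCM-16 WAV file
#'
#' @param clip an [audio_clip()]; amplitudes are clipped to `[-1, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  s <- pmax(pmin(clip$samples, 1), -1)
  ints <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(ints) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
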