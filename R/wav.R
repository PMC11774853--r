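# Audio rendering. Voices are simple deterministic oscillators -- a decaying
# two-partial burst for the snare, a low decaying sine for the bass drum,
# plain sines for melody notes -- because only event timing, pitch and the
# referent mix matter to the pipeline, not timbre. Everything is rendered at
# the grid tempo (one tick = 60/bpm/ticks_per_quarter seconds).

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]` (values outside are clipped).
#' @param path Output path.
#' @param sample_rate Samples per second.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 22050L) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeBin(charToRaw("RIFF"), con)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeBin(charToRaw("WAVE"), con)
  writeBin(charToRaw("fmt "), con)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeBin(charToRaw("data"), con)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal reader for files produced by [write_wav()] / [render_wav()].
#'
#' @param path A WAV file.
#' @return A list with `samples` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 12L)
  if (rawToChar(hdr[1:4]) != "RIFF" || rawToChar(hdr[9:12]) != "WAVE") {
    stop("not a RIFF/WAVE file")
  }
  sample_rate <- NA_integer_
  repeat {
    id <- rawToChar(readBin(con, "raw", 4L))
    size <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", size / 2L, size = 2, endian = "little",
                     signed = FALSE)
      sample_rate <- fmt[3] + fmt[4] * 65536L
    } else if (id == "data") {
      pcm <- readBin(con, "integer", size / 2L, size = 2, endian = "little")
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}

# linear fade-in/out envelope; fade_frac of the length on each side
fade_envelope <- function(n, fade_frac) {
  nf <- max(1L, floor(n * fade_frac))
  env <- rep(1, n)
  env[seq_len(nf)] <- seq(0, 1, length.out = nf + 1L)[-1L]
  env[n - seq_len(nf) + 1L] <- seq(0, 1, length.out = nf + 1L)[-1L]
  env
}

# drone: sine one octave below the root, one whole measure long, linear
# fade in and out each 1/20 of the note duration
drone_wave <- function(root, dur_sec, sample_rate, fade_frac = 1 / 20) {
  n <- round(dur_sec * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  sin(2 * pi * midi_to_freq(root - 12L) * t) * fade_envelope(n, fade_frac)
}

snare_wave <- function(sample_rate) {
  n <- round(0.05 * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  (sin(2 * pi * 331 * t) + 0.6 * sin(2 * pi * 507 * t)) * exp(-t / 0.012)
}

kick_wave <- function(sample_rate) {
  n <- round(0.09 * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  sin(2 * pi * 72 * t) * exp(-t / 0.03)
}

tone_wave <- function(freq, dur_sec, sample_rate) {
  n <- round(dur_sec * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  sin(2 * pi * freq * t) * fade_envelope(n, 0.02)
}

add_at <- function(buf, wave, start_sample, gain) {
  idx <- start_sample + seq_along(wave)
  keep <- idx <= length(buf)
  buf[idx[keep]] <- buf[idx[keep]] + gain * wave[keep]
  buf
}

#' Render a stimulus to a WAV file
#'
#' Renders the pattern's events with simple deterministic synth voices and,
#' when the referent flag is set, the referent stream: a bass-drum hit on
#' every downbeat for rhythm, or a drone -- a sine one octave below the scale
#' root, lasting one full measure per measure, with linear fade-in and
#' fade-out each 1/20 of its duration -- mixed at -15 dB relative to the
#' pattern events for melody.
#'
#' @param stimulus A `stimulus` object or a bare pattern.
#' @param path Output WAV path.
#' @param sample_rate Samples per second, at least 8000. Default 22050.
#' @param referent Add the referent stream; overridden by the stimulus' own
#'   flag when present.
#' @return `path`, invisibly.
#' @export
render_wav <- function(stimulus, path, sample_rate = 22050L,
                       referent = FALSE) {
  if (sample_rate < 8000) stop("sample_rate must be at least 8000 Hz")
  pat <- if (inherits(stimulus, "stimulus")) stimulus$pattern else stimulus
  if (inherits(stimulus, "stimulus")) referent <- isTRUE(stimulus$referent)
  grid <- pat$grid
  sec_per_tick <- tick_seconds(grid)
  span <- pattern_span(pat)
  buf <- numeric(round(span * sec_per_tick * sample_rate))
  event_gain <- 0.45
  onsets <- pattern_onsets(pat)
  starts <- round(onsets * sec_per_tick * sample_rate)

  if (inherits(pat, "rhythm_pattern")) {
    hit <- snare_wave(sample_rate)
    for (s in starts) buf <- add_at(buf, hit, s, event_gain)
    if (referent) {
      kick <- kick_wave(sample_rate)
      tpm <- ticks_per_measure(grid)
      for (m in seq(0L, span - 1L, by = tpm)) {
        buf <- add_at(buf, kick, round(m * sec_per_tick * sample_rate),
                      event_gain)
      }
    }
  } else {
    dur <- pat$note_duration * sec_per_tick
    for (i in seq_along(pat$pitches)) {
      buf <- add_at(buf, tone_wave(midi_to_freq(pat$pitches[i]), dur,
                                   sample_rate),
                    starts[i], event_gain)
    }
    if (referent) {
      tpm <- ticks_per_measure(grid)
      measure_sec <- tpm * sec_per_tick
      drone <- drone_wave(pat$root, measure_sec, sample_rate)
      drone_gain <- event_gain * 10^(-15 / 20)   # -15 dB re pattern events
      for (m in seq(0L, span - 1L, by = tpm)) {
        buf <- add_at(buf, drone, round(m * sec_per_tick * sample_rate),
                      drone_gain)
      }
    }
  }
  write_wav(buf, path, sample_rate)
}
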