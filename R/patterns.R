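#' Tick grid for quantised musical time
#'
#' All patterns live on a shared integer tick grid. The default resolution is
#' 8 ticks per quarter note, so one tick is one 32nd note: the smallest timing
#' manipulation used anywhere in the pipeline (0.125 quarter note) is exactly
#' one tick, a 16th note is two ticks, and one 4/4 measure is 32 ticks. No
#' floating-point time exists upstream of audio rendering.
#'
#' @param ticks_per_quarter Integer ticks per quarter note. Default 8.
#' @param beats_per_measure Beats per measure (quarter notes). Default 4.
#' @param tempo_bpm Tempo in quarter notes per minute. Default 160.
#' @return An object of class `tick_grid`.
#' @examples
#' g <- tick_grid()
#' ticks_per_measure(g)  # 32
#' @export
tick_grid <- function(ticks_per_quarter = 8L, beats_per_measure = 4L,
                      tempo_bpm = 160) {
  stopifnot(ticks_per_quarter >= 1, beats_per_measure >= 1, tempo_bpm > 0)
  structure(
    list(ticks_per_quarter = as.integer(ticks_per_quarter),
         beats_per_measure = as.integer(beats_per_measure),
         tempo_bpm = tempo_bpm),
    class = "tick_grid"
  )
}

#' @rdname tick_grid
#' @param grid A `tick_grid`.
#' @export
ticks_per_measure <- function(grid) {
  grid$ticks_per_quarter * grid$beats_per_measure
}

#' Seconds per tick at the grid tempo
#' @param grid A `tick_grid`.
#' @return Duration of one tick in seconds.
#' @export
tick_seconds <- function(grid) {
  60 / grid$tempo_bpm / grid$ticks_per_quarter
}

# Interval palette for rhythm targets: 8th, quarter, dotted quarter, half
# note, in ticks at 8 ticks/quarter.
target_interval_choices <- c(4L, 8L, 12L, 16L)

# Major-pentatonic degrees available to melody targets, in semitones relative
# to the root: perfect 5th below up to and including the perfect 5th above.
pentatonic_degrees <- c(-5L, -3L, 0L, 2L, 4L, 7L)

# Pitch classes (mod 12, relative to the root) of the major pentatonic scale.
pentatonic_pitch_classes <- c(0L, 2L, 4L, 7L, 9L)

#' Rhythm pattern on the tick grid
#'
#' A rhythm pattern is an ordered vector of inter-onset intervals (IOIs) in
#' ticks. The first onset is always at tick 0 (the downbeat of the first
#' measure), so a pattern with `k` intervals has `k + 1` sounded events at
#' onsets `c(0, cumsum(intervals))`.
#'
#' @param intervals Integer vector of IOIs in ticks, each > 0.
#' @param grid A `tick_grid`.
#' @return An object of class `rhythm_pattern`.
#' @examples
#' p <- rhythm_pattern(c(8, 8, 8, 8))
#' pattern_onsets(p)
#' @export
rhythm_pattern <- function(intervals, grid = tick_grid()) {
  intervals <- as.integer(intervals)
  if (length(intervals) < 1 || any(intervals <= 0)) {
    stop("rhythm intervals must be a non-empty vector of positive ticks")
  }
  structure(
    list(intervals = intervals, grid = grid),
    class = "rhythm_pattern"
  )
}

#' Melody pattern on the tick grid
#'
#' An ordered vector of MIDI pitches, each sounding for `note_duration` ticks
#' (default 4, i.e. one 8th note) back to back, so a 16-note melody spans
#' exactly two 4/4 measures.
#'
#' @param pitches Integer vector of MIDI note numbers.
#' @param root MIDI note number of the scale root (the first pitch for
#'   targets).
#' @param note_duration Note duration in ticks. Default 4.
#' @param grid A `tick_grid`.
#' @return An object of class `melody_pattern`.
#' @export
melody_pattern <- function(pitches, root, note_duration = 4L,
                           grid = tick_grid()) {
  pitches <- as.integer(pitches)
  root <- as.integer(root)
  if (length(pitches) < 1) stop("melody needs at least one pitch")
  if (any(pitches < 0 | pitches > 127)) stop("pitches must be MIDI notes 0-127")
  structure(
    list(pitches = pitches, root = root,
         note_duration = as.integer(note_duration), grid = grid),
    class = "melody_pattern"
  )
}

#' Onset ticks of a pattern
#'
#' @param pattern A `rhythm_pattern` or `melody_pattern`.
#' @return Integer vector of onset times in ticks, starting at 0.
#' @export
pattern_onsets <- function(pattern) {
  UseMethod("pattern_onsets")
}

#' @export
pattern_onsets.rhythm_pattern <- function(pattern) {
  c(0L, cumsum(pattern$intervals))
}

#' @export
pattern_onsets.melody_pattern <- function(pattern) {
  as.integer(seq_along(pattern$pitches) - 1L) * pattern$note_duration
}

#' Pattern span in ticks, rounded up to whole measures
#'
#' The audible span of a pattern: the last event onset plus one event
#' duration, rounded up to a whole measure so that referent streams (bass
#' drum on every downbeat, one drone per measure) tile it exactly. A 16-note
#' melody spans 64 ticks (2 measures); rhythm targets span at most 96 ticks
#' (3 measures).
#'
#' @param pattern A `rhythm_pattern` or `melody_pattern`.
#' @return Span in ticks (a multiple of the measure length).
#' @export
pattern_span <- function(pattern) {
  onsets <- pattern_onsets(pattern)
  tpm <- ticks_per_measure(pattern$grid)
  as.integer(tpm * ceiling((max(onsets) + 1L) / tpm))
}

#' @export
print.rhythm_pattern <- function(x, ...) {
  cat("<rhythm_pattern> ", length(x$intervals), " intervals (",
      length(x$intervals) + 1L, " events): ",
      paste(x$intervals, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.melody_pattern <- function(x, ...) {
  cat("<melody_pattern> root ", x$root, ", ", length(x$pitches),
      " pitches: ", paste(x$pitches, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Encode or decode a pattern as a manifest string
#'
#' Patterns are stored in manifest CSVs as a space-separated string of
#' intervals (rhythm) or pitches (melody); the round trip is lossless.
#'
#' @param pattern A pattern object.
#' @return `pattern_to_string()`: a character scalar.
#' @export
pattern_to_string <- function(pattern) {
  if (inherits(pattern, "rhythm_pattern")) {
    paste(pattern$intervals, collapse = " ")
  } else if (inherits(pattern, "melody_pattern")) {
    paste(pattern$pitches, collapse = " ")
  } else {
    stop("not a pattern object")
  }
}

#' @rdname pattern_to_string
#' @param x Character scalar as produced by [pattern_to_string()].
#' @param domain `"rhythm"` or `"melody"`.
#' @param root Scale root (melody only).
#' @return `string_to_pattern()`: the reconstructed pattern object.
#' @export
string_to_pattern <- function(x, domain, root = NA_integer_) {
  vals <- as.integer(strsplit(trimws(x), "\\s+")[[1]])
  if (anyNA(vals)) stop("malformed pattern string: ", x)
  if (domain == "rhythm") {
    rhythm_pattern(vals)
  } else if (domain == "melody") {
    melody_pattern(vals, root = root)
  } else {
    stop("unknown domain: ", domain)
  }
}

#' Frequency of a MIDI note number
#'
#' Standard 12-TET tuning with A4 (MIDI 69) at 440 Hz.
#'
#' @param midi MIDI note number(s).
#' @return Frequency in Hz.
#' @examples
#' midi_to_freq(69)  # 440
#' midi_to_freq(48)  # ~130.81, the drone for a root at middle C
#' @export
midi_to_freq <- function(midi) {
  440 * 2^((midi - 69) / 12)
}
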