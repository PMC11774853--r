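# Standard MIDI File plumbing. Format 0, one track, division equal to the
# tick grid's ticks-per-quarter, so onset times in the file are exactly the
# pattern's grid ticks. Percussion (snare key 37, bass-drum referent key 36)
# goes on channel 10; melodies on channel 1 with program 1 (acoustic piano).

midi_vlq <- function(x) {
  # variable-length quantity, most significant septet first
  stopifnot(x >= 0)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  # continuation bit on all but the last septet
  if (length(bytes) > 1) {
    bytes[-length(bytes)] <- bitwOr(bytes[-length(bytes)], 128L)
  }
  as.raw(bytes)
}

midi_uint <- function(x, nbytes) {
  out <- raw(nbytes)
  for (i in nbytes:1) {
    out[i] <- as.raw(x %% 256L)
    x <- x %/% 256L
  }
  out
}

#' Write a stimulus to a Standard MIDI File
#'
#' Rhythm patterns are written as snare hits (GM percussion key 37) on the
#' percussion channel, with a bass-drum (key 36) event on the first beat of
#' every measure when the referent flag is set. Melody patterns are written
#' on a melodic channel with program 1; the melodic drone referent exists
#' only in rendered audio (see [render_wav()]), matching how such stimuli are
#' produced, so the referent flag does not change a melody MIDI file.
#'
#' @param stimulus A `stimulus` object (see [stimulus_record()]), or a bare
#'   pattern (then `referent = FALSE`).
#' @param path Output file path.
#' @param referent Add the referent stream (rhythm only). Ignored when
#'   `stimulus` carries its own referent flag.
#' @return `path`, invisibly.
#' @seealso [read_midi()] for the round-trip reader.
#' @export
write_midi <- function(stimulus, path, referent = FALSE) {
  pat <- if (inherits(stimulus, "stimulus")) stimulus$pattern else stimulus
  if (inherits(stimulus, "stimulus")) referent <- isTRUE(stimulus$referent)
  grid <- pat$grid
  tempo_us <- round(60e6 / grid$tempo_bpm)

  if (inherits(pat, "rhythm_pattern")) {
    onsets <- pattern_onsets(pat)
    dur <- 2L                       # 16th-note gate for drum hits
    ev <- data.frame(tick = onsets, key = 37L, channel = 9L)
    if (referent) {
      beats <- seq(0L, max(onsets), by = ticks_per_measure(grid))
      ev <- rbind(ev, data.frame(tick = beats, key = 36L, channel = 9L))
    }
  } else if (inherits(pat, "melody_pattern")) {
    onsets <- pattern_onsets(pat)
    dur <- pat$note_duration
    ev <- data.frame(tick = onsets, key = pat$pitches, channel = 0L)
  } else {
    stop("stimulus does not carry a rhythm or melody pattern")
  }

  # note-on / note-off pairs, stable order: time, then off before on at
  # equal time so back-to-back melody notes re-trigger cleanly
  msgs <- rbind(
    data.frame(tick = ev$tick, status = 0x90L + ev$channel, key = ev$key,
               vel = 96L, prio = 2L),
    data.frame(tick = ev$tick + dur, status = 0x80L + ev$channel,
               key = ev$key, vel = 0L, prio = 1L)
  )
  msgs <- msgs[order(msgs$tick, msgs$prio, msgs$key), ]

  track <- c(
    as.raw(c(0x00, 0xFF, 0x51, 0x03)), midi_uint(tempo_us, 3L),       # tempo
    as.raw(c(0x00, 0xFF, 0x58, 0x04)),
    as.raw(c(grid$beats_per_measure, 0x02, 0x18, 0x08))               # 4/4
  )
  if (inherits(pat, "melody_pattern")) {
    track <- c(track, as.raw(c(0x00, 0xC0, 0x00)))                    # piano
  }
  prev <- 0L
  for (i in seq_len(nrow(msgs))) {
    track <- c(track, midi_vlq(msgs$tick[i] - prev),
               as.raw(c(msgs$status[i], msgs$key[i], msgs$vel[i])))
    prev <- msgs$tick[i]
  }
  track <- c(track, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))                # EOT

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MThd"), con)
  writeBin(midi_uint(6L, 4L), con)
  writeBin(midi_uint(0L, 2L), con)                                    # format 0
  writeBin(midi_uint(1L, 2L), con)                                    # 1 track
  writeBin(midi_uint(grid$ticks_per_quarter, 2L), con)
  writeBin(charToRaw("MTrk"), con)
  writeBin(midi_uint(length(track), 4L), con)
  writeBin(track, con)
  invisible(path)
}

#' Read note events back from a Standard MIDI File
#'
#' A minimal reader sufficient for round-tripping files written by
#' [write_midi()] (single track, supports running status). Returns the
#' note-on events.
#'
#' @param path A Standard MIDI File.
#' @return A data frame with columns `tick`, `channel` (0-based), `key`,
#'   `velocity`, plus attributes `division` and `tempo_us`.
#' @export
read_midi <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  u <- function(idx) as.integer(bytes[idx])
  be <- function(from, n) sum(u(from:(from + n - 1L)) * 256^((n - 1L):0))
  if (rawToChar(bytes[1:4]) != "MThd") stop("not a Standard MIDI File")
  division <- be(13L, 2L)
  pos <- 15L
  if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") stop("missing MTrk chunk")
  len <- be(pos + 4L, 4L)
  i <- pos + 8L
  end <- i + len
  tick <- 0
  tempo_us <- NA_real_
  status <- NA_integer_
  out <- list()
  while (i < end) {
    # delta time VLQ
    dt <- 0
    repeat {
      b <- u(i); i <- i + 1L
      dt <- dt * 128 + b %% 128L
      if (b < 128L) break
    }
    tick <- tick + dt
    b <- u(i)
    if (b >= 128L) { status <- b; i <- i + 1L } # else running status
    if (status == 0xFF) {
      type <- u(i); mlen <- u(i + 1L); i <- i + 2L
      if (type == 0x51) tempo_us <- be(i, mlen)
      i <- i + mlen
      if (type == 0x2F) break
    } else if (status %/% 16L %in% c(0x8, 0x9, 0xA, 0xB, 0xE)) {
      if (status %/% 16L == 0x9 && u(i + 1L) > 0L) {
        out[[length(out) + 1L]] <- c(tick, status %% 16L, u(i), u(i + 1L))
      }
      i <- i + 2L
    } else if (status %/% 16L %in% c(0xC, 0xD)) {
      i <- i + 1L
    } else {
      stop("unsupported MIDI status byte: ", status)
    }
  }
  notes <- as.data.frame(do.call(rbind, out))
  names(notes) <- c("tick", "channel", "key", "velocity")
  attr(notes, "division") <- division
  attr(notes, "tempo_us") <- tempo_us
  notes
}
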