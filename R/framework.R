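# Framework classification. Rhythm: Longuet-Higgins & Lee syncopation in
# the Fitch & Rosenfeld formulation (LHL-FR), minimised over metrical phase
# shifts; a target-vs-variant score difference of 4 or more marks the
# manipulation as out-of-framework. Melody: major-pentatonic key membership
# of the changed note.

#' Metrical weights of one 4/4 measure at 32nd-note resolution
#'
#' Integer weights from the binary subdivision tree: the downbeat weighs 0,
#' the half-note position -1, quarters -2, 8ths -3, 16ths -4 and 32nds -5.
#' Weight depends only on the tick position modulo the measure length, so
#' one measure's vector serves any pattern length.
#'
#' @param grid A `tick_grid` (must subdivide binarily, i.e. ticks per
#'   quarter a power of two).
#' @return Integer vector of length `ticks_per_measure(grid)`; element `i`
#'   is the weight of tick `i - 1`.
#' @export
metrical_weights <- function(grid = tick_grid()) {
  tpm <- ticks_per_measure(grid)
  depth <- log2(tpm)
  if (depth != round(depth)) stop("measure length must be a power of two ticks")
  w <- integer(tpm)
  for (i in 2:tpm) {
    t <- i - 1L
    k <- 0L
    while (t %% 2L == 0L) { k <- k + 1L; t <- t %/% 2L }
    w[i] <- k - as.integer(depth)
  }
  w
}

# core scorer on raw onset ticks: for each onset, the silent span runs to
# the next onset (exclusive) or, for the last onset, to frame_end; if the
# loudest silent tick w_r is at least the onset's weight w_n, the pair
# contributes w_r - w_n
lhl_score_onsets <- function(onsets, frame_end, weights) {
  tpm <- length(weights)
  w_of <- function(t) weights[t %% tpm + 1L]
  bounds <- c(onsets[-1L], frame_end)
  total <- 0L
  for (i in seq_along(onsets)) {
    if (onsets[i] + 1L > bounds[i] - 1L) next
    span <- seq.int(onsets[i] + 1L, bounds[i] - 1L)
    w_r <- max(w_of(span))
    w_n <- w_of(onsets[i])
    if (w_r >= w_n) total <- total + (w_r - w_n)
  }
  total
}

#' LHL-FR syncopation score of a rhythm pattern
#'
#' Places the pattern's onsets on the metrical weight grid, optionally
#' phase-shifted, and scores each note against the loudest silent position
#' in the rest that follows it: whenever a note is followed by a silent tick
#' of equal or higher metrical weight, the pair contributes the weight
#' difference; the score is the sum over all such pairs (never negative).
#' The final onset's rest runs to the end of the measure frame containing
#' it.
#'
#' @param pattern A `rhythm_pattern` quantised to the grid.
#' @param shift_ticks Phase shift in ticks; must be a multiple of a 16th
#'   note (2 ticks) in `0, 2, ..., 30`.
#' @return Integer score, >= 0.
#' @examples
#' lhl_fr_score(rhythm_pattern(c(8, 8, 8, 8)))   # on-beat quarters: 0
#' @export
lhl_fr_score <- function(pattern, shift_ticks = 0L) {
  stopifnot(inherits(pattern, "rhythm_pattern"))
  grid <- pattern$grid
  tpm <- ticks_per_measure(grid)
  sixteenth <- grid$ticks_per_quarter %/% 4L
  if (shift_ticks %% sixteenth != 0L || shift_ticks < 0L ||
      shift_ticks >= tpm) {
    stop("shift_ticks must be a 16th-note multiple within one measure")
  }
  onsets <- pattern_onsets(pattern) + as.integer(shift_ticks)
  frame_end <- as.integer(tpm * ceiling((max(onsets) + 1L) / tpm))
  lhl_score_onsets(onsets, frame_end, metrical_weights(grid))
}

#' Minimum LHL-FR score over all 16th-note phase shifts
#'
#' Rhythms presented without a metrical referent do not enforce a metre, and
#' listeners tend to reinterpret highly syncopated patterns in the phase
#' that makes them least syncopated. This evaluates [lhl_fr_score()] at all
#' 16 shifts of one measure (0, 2, ..., 30 ticks) and keeps the lowest.
#'
#' @param pattern A `rhythm_pattern`.
#' @return An object of class `syncopation_result`: a list with
#'   `score_by_shift` (named integer vector over the 16 shifts, names are
#'   shift ticks), `min_score`, `min_shift` (ticks; ties resolve to the
#'   smallest shift) and `phase0_score`.
#' @export
min_syncopation <- function(pattern) {
  grid <- pattern$grid
  sixteenth <- grid$ticks_per_quarter %/% 4L
  shifts <- seq.int(0L, ticks_per_measure(grid) - sixteenth, by = sixteenth)
  scores <- vapply(shifts, function(s) lhl_fr_score(pattern, s), integer(1))
  names(scores) <- shifts
  structure(
    list(score_by_shift = scores,
         min_score = min(scores),
         min_shift = shifts[which.min(scores)],
         phase0_score = scores[[1L]]),
    class = "syncopation_result"
  )
}

#' @export
print.syncopation_result <- function(x, ...) {
  cat("<syncopation_result> min", x$min_score, "at shift", x$min_shift,
      "ticks (phase 0:", x$phase0_score, ")\n")
  invisible(x)
}

#' Framework classification of a manipulated rhythm pattern
#'
#' The framework impact of a rhythm manipulation is the absolute difference
#' in LHL-FR syncopation between variant and target; a difference of
#' `threshold` (default 4) or larger is out-of-framework -- the magnitude of
#' e.g. a downbeat being offset by a 32nd note. Stimuli without a referent
#' are scored by the shift-minimised score (no enforced metre); stimuli
#' whose bass-drum referent pins down the metre are scored at phase 0. The
#' `phase_mode` switch overrides this per-referent default.
#'
#' @param target,variant `rhythm_pattern`s.
#' @param referent Does the stimulus pair carry the metrical referent?
#' @param threshold Out-of-framework cutoff on the absolute score
#'   difference. Default 4.
#' @param phase_mode `"per_referent"` (default), `"always_min"`, or
#'   `"always_phase0"`.
#' @return `"in"` or `"out"`.
#' @seealso [syncopation_difference()] for the underlying scores.
#' @export
rhythm_framework_class <- function(target, variant, referent = FALSE,
                                   threshold = 4L,
                                   phase_mode = c("per_referent",
                                                  "always_min",
                                                  "always_phase0")) {
  d <- syncopation_difference(target, variant, referent = referent,
                              phase_mode = phase_mode)
  if (d$sync_diff >= threshold) "out" else "in"
}

#' @rdname rhythm_framework_class
#' @return `syncopation_difference()`: a list with `sync_target`,
#'   `sync_variant`, `sync_diff` (absolute difference) and `min_shift` (the
#'   variant's minimising shift, in ticks).
#' @export
syncopation_difference <- function(target, variant, referent = FALSE,
                                   phase_mode = c("per_referent",
                                                  "always_min",
                                                  "always_phase0")) {
  phase_mode <- match.arg(phase_mode)
  use_phase0 <- switch(phase_mode,
                       per_referent = isTRUE(referent),
                       always_min = FALSE,
                       always_phase0 = TRUE)
  st <- min_syncopation(target)
  sv <- min_syncopation(variant)
  s_t <- if (use_phase0) st$phase0_score else st$min_score
  s_v <- if (use_phase0) sv$phase0_score else sv$min_score
  list(sync_target = s_t, sync_variant = s_v,
       sync_diff = abs(s_v - s_t), min_shift = sv$min_shift)
}

#' Framework classification of a manipulated melody pattern
#'
#' A melody manipulation is out-of-framework when the changed note leaves
#' the major pentatonic scale of the target's root, i.e. its pitch class
#' relative to the root (mod 12, so octave displacement is irrelevant) is
#' not one of {0, 2, 4, 7, 9}.
#'
#' @param target,variant `melody_pattern`s differing in exactly one pitch.
#' @return `"in"` or `"out"`.
#' @export
melody_framework_class <- function(target, variant) {
  stopifnot(inherits(target, "melody_pattern"),
            inherits(variant, "melody_pattern"))
  changed <- which(target$pitches != variant$pitches)
  if (length(changed) != 1L) {
    stop("variant must differ from target in exactly one pitch, found ",
         length(changed))
  }
  pc <- (variant$pitches[changed] - target$root) %% 12L
  if (pc %in% pentatonic_pitch_classes) "in" else "out"
}

#' Attach framework classification to a stimulus manifest
#'
#' Adds `sync_target`, `sync_variant`, `sync_diff`, `min_shift` (rhythm
#' rows; `NA` for melody) and `framework_class` (`"in"`/`"out"` for
#' manipulated rows, `"n/a"` for targets).
#'
#' @param set A stimulus manifest data frame (see [build_stimulus_set()]).
#' @param phase_mode,threshold See [rhythm_framework_class()].
#' @return The manifest with classification columns filled in.
#' @export
classify_framework <- function(set, phase_mode = "per_referent",
                               threshold = 4L) {
  set$sync_target <- NA_integer_
  set$sync_variant <- NA_integer_
  set$sync_diff <- NA_integer_
  set$min_shift <- NA_integer_
  set$framework_class <- "n/a"
  sync_cache <- new.env(parent = emptyenv())
  cached_sync <- function(str) {
    if (is.null(sync_cache[[str]])) {
      sync_cache[[str]] <- min_syncopation(string_to_pattern(str, "rhythm"))
    }
    sync_cache[[str]]
  }

  manip <- which(set$variant == "manipulated")
  for (i in manip) {
    t_row <- which(set$domain == set$domain[i] &
                   set$target_id == set$target_id[i] &
                   set$variant == "target")[1L]
    if (set$domain[i] == "rhythm") {
      st <- cached_sync(set$pattern[t_row])
      sv <- cached_sync(set$pattern[i])
      use_phase0 <- switch(phase_mode,
                           per_referent = set$referent[i],
                           always_min = FALSE,
                           always_phase0 = TRUE,
                           stop("unknown phase_mode: ", phase_mode))
      s_t <- if (use_phase0) st$phase0_score else st$min_score
      s_v <- if (use_phase0) sv$phase0_score else sv$min_score
      set$sync_target[i] <- s_t
      set$sync_variant[i] <- s_v
      set$sync_diff[i] <- abs(s_v - s_t)
      set$min_shift[i] <- sv$min_shift
      set$framework_class[i] <- if (abs(s_v - s_t) >= threshold) "out" else "in"
    } else {
      target <- string_to_pattern(set$pattern[t_row], "melody",
                                  root = set$root[t_row])
      variant <- string_to_pattern(set$pattern[i], "melody",
                                   root = set$root[i])
      set$framework_class[i] <- melody_framework_class(target, variant)
    }
  }
  set
}
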