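# Stimulus generation: constrained random targets, single-event
# manipulations with compensation, contour classification, and assembly of
# the balanced stimulus set.

#' Generate a random rhythm target pattern
#'
#' Inter-onset intervals are drawn uniformly from {8th, quarter, dotted
#' quarter, half note} = {4, 8, 12, 16} ticks, appended sequentially. A draw
#' that would push the final onset beyond the three-measure limit (96 ticks)
#' is redrawn from the still-feasible subset; generation ends when nothing
#' fits or 12 intervals are reached. Attempts ending with fewer than 8
#' intervals are discarded and resampled, so every returned target has 8-12
#' intervals (9-13 events), starts on the downbeat, and fits in three 4/4
#' measures.
#'
#' Uses the session RNG; call `set.seed()` for reproducibility.
#'
#' @param grid A `tick_grid`.
#' @return A `rhythm_pattern`.
#' @export
generate_rhythm_target <- function(grid = tick_grid()) {
  limit <- 3L * ticks_per_measure(grid)   # final onset must stay inside
  repeat {
    intervals <- integer(0)
    span <- 0L
    while (length(intervals) < 12L) {
      feasible <- target_interval_choices[span + target_interval_choices < limit]
      if (length(feasible) == 0L) break
      iv <- feasible[sample.int(length(feasible), 1L)]
      intervals <- c(intervals, iv)
      span <- span + iv
    }
    if (length(intervals) >= 8L) {
      return(rhythm_pattern(intervals, grid = grid))
    }
  }
}

#' Generate a random melody target pattern
#'
#' The root is drawn uniformly from the 4th octave (MIDI 60-71) and defines
#' a major pentatonic degree set of six notes spanning the perfect 5th below
#' to the perfect 5th above the root ({-5, -3, 0, +2, +4, +7} semitones).
#' The first of the 16 pitches is always the root; each subsequent pitch is
#' drawn uniformly from the degrees whose melodic interval to the preceding
#' note is between 2 and 12 semitones in absolute size (which also forbids
#' immediate repeats). Every degree has at least one legal successor, so
#' generation never dead-ends.
#'
#' @param grid A `tick_grid`.
#' @param n_notes Number of notes. Default 16 (two 4/4 measures of 8ths).
#' @return A `melody_pattern`.
#' @export
generate_melody_target <- function(grid = tick_grid(), n_notes = 16L) {
  root <- 59L + sample.int(12L, 1L)       # uniform on 60..71
  scale_notes <- root + pentatonic_degrees
  pitches <- integer(n_notes)
  pitches[1L] <- root
  for (i in 2L:n_notes) {
    step <- abs(scale_notes - pitches[i - 1L])
    candidates <- scale_notes[step >= 2L & step <= 12L]
    pitches[i] <- candidates[sample.int(length(candidates), 1L)]
  }
  melody_pattern(pitches, root = root, grid = grid)
}

#' Apply a single-event manipulation with compensation
#'
#' Changes the interval at `position` by `delta` and the following interval
#' by `-delta`, so exactly one event moves (rhythm) or one pitch changes
#' (melody) and everything after the manipulated pair is untouched. When
#' `position` is the last interval there is nothing to compensate, and the
#' pattern's span changes by `delta`.
#'
#' For melodies, manipulating interval `position` means shifting the pitch
#' of the note that terminates it (`pitches[position + 1]`) by `delta`
#' semitones; the following interval absorbs the change automatically
#' because the next pitch stays put.
#'
#' @param pattern A `rhythm_pattern` or `melody_pattern`.
#' @param delta Signed change: ticks for rhythm (±1 = 32nd, ±2 = 16th),
#'   semitones for melody (±2, ±3).
#' @param position Interval index, 1-based.
#' @return The manipulated pattern (same class as the input).
#' @export
apply_manipulation <- function(pattern, delta, position) {
  delta <- as.integer(delta)
  position <- as.integer(position)
  if (inherits(pattern, "rhythm_pattern")) {
    n <- length(pattern$intervals)
    if (position < 1L || position > n) stop("position out of range")
    intervals <- pattern$intervals
    intervals[position] <- intervals[position] + delta
    if (position < n) {
      intervals[position + 1L] <- intervals[position + 1L] - delta
    }
    if (any(intervals <= 0L)) {
      stop("manipulation would produce a non-positive interval")
    }
    rhythm_pattern(intervals, grid = pattern$grid)
  } else if (inherits(pattern, "melody_pattern")) {
    n <- length(pattern$pitches) - 1L
    if (position < 1L || position > n) stop("position out of range")
    pitches <- pattern$pitches
    pitches[position + 1L] <- pitches[position + 1L] + delta
    melody_pattern(pitches, root = pattern$root,
                   note_duration = pattern$note_duration,
                   grid = pattern$grid)
  } else {
    stop("not a pattern object")
  }
}

#' Compute the contour of a pattern
#'
#' One arrow per position from the second element on, comparing each element
#' to its predecessor: `"up"`, `"down"`, or `"same"`. Melodies compare
#' pitches (15 arrows for a 16-note target); rhythms compare inter-onset
#' interval durations (one fewer arrow than intervals).
#'
#' @param pattern A pattern object with at least 2 comparable elements.
#' @return Character vector of arrows.
#' @examples
#' compute_contour(rhythm_pattern(c(8, 8, 16)))   # "same" "up"
#' @export
compute_contour <- function(pattern) {
  values <- if (inherits(pattern, "rhythm_pattern")) {
    pattern$intervals
  } else if (inherits(pattern, "melody_pattern")) {
    pattern$pitches
  } else {
    stop("not a pattern object")
  }
  if (length(values) < 2L) stop("pattern too short for a contour")
  c("down", "same", "up")[sign(diff(values)) + 2L]
}

#' Did a manipulation change the contour?
#'
#' Compares the contours of target and variant arrow by arrow over their
#' common prefix (lengths only differ in degenerate cases; compensated
#' manipulations preserve element counts).
#'
#' @param target,variant Patterns of the same domain.
#' @return `TRUE` iff any arrow differs.
#' @export
contour_changed <- function(target, variant) {
  if (!identical(class(target), class(variant))) {
    stop("patterns are not comparable across domains")
  }
  a <- compute_contour(target)
  b <- compute_contour(variant)
  k <- min(length(a), length(b))
  any(a[seq_len(k)] != b[seq_len(k)])
}

# manipulation palette per domain: delta, size label, sign label
manipulation_palette <- function(domain) {
  if (domain == "rhythm") {
    data.frame(delta = c(1L, -1L, 2L, -2L),
               manipulation_size = c("small", "small", "large", "large"),
               manipulation_sign = c("+", "-", "+", "-"))
  } else {
    data.frame(delta = c(2L, -2L, 3L, -3L),
               manipulation_size = c("small", "small", "large", "large"),
               manipulation_sign = c("+", "-", "+", "-"))
  }
}

n_intervals <- function(pattern) {
  if (inherits(pattern, "rhythm_pattern")) length(pattern$intervals)
  else length(pattern$pitches) - 1L
}

#' Build a balanced stimulus set for one domain
#'
#' For each target and each of the four manipulation types (±1/±2 ticks for
#' rhythm, ±2/±3 semitones for melody), the manipulation is enumerated at
#' every interval position and each variant is classified by contour impact;
#' one contour-changed and one contour-unchanged variant are then drawn at
#' random per type. With the target itself this gives 9 stimuli per target,
#' duplicated with and without the referent: 18 per target, so the default
#' 16 targets yield 288 records. A target for which some manipulation type
#' admits no contour-changed (or no unchanged) variant is discarded and
#' regenerated rather than relaxing the balance (a message reports how many
#' regenerations occurred).
#'
#' @param n_targets Number of targets. Default 16.
#' @param domain `"rhythm"` or `"melody"`.
#' @param seed Optional integer seed for exact reproducibility.
#' @param classify Attach framework classification columns via
#'   [classify_framework()]. Default `TRUE`.
#' @param phase_mode,threshold Passed to [classify_framework()].
#' @param grid A `tick_grid`.
#' @return A stimulus manifest: a data frame with one row per
#'   `stimulus_record()`, patterns encoded as strings (see
#'   [pattern_to_string()]).
#' @export
build_stimulus_set <- function(n_targets = 16L,
                               domain = c("rhythm", "melody"),
                               seed = NULL, classify = TRUE,
                               phase_mode = "per_referent", threshold = 4L,
                               grid = tick_grid()) {
  domain <- match.arg(domain)
  if (n_targets < 1L) stop("n_targets must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  palette <- manipulation_palette(domain)
  rows <- list()
  n_regenerated <- 0L

  for (tid in seq_len(n_targets)) {
    repeat {
      target <- if (domain == "rhythm") generate_rhythm_target(grid)
                else generate_melody_target(grid)
      k <- n_intervals(target)
      # candidate variants per type, classified by contour impact
      picks <- vector("list", nrow(palette))
      ok <- TRUE
      for (m in seq_len(nrow(palette))) {
        variants <- lapply(seq_len(k), function(p) {
          apply_manipulation(target, palette$delta[m], p)
        })
        changed <- vapply(variants, contour_changed, logical(1),
                          target = target)
        if (any(changed) && !all(changed)) {
          pos_c <- which(changed)
          pos_u <- which(!changed)
          picks[[m]] <- list(
            changed = variants[[pos_c[sample.int(length(pos_c), 1L)]]],
            unchanged = variants[[pos_u[sample.int(length(pos_u), 1L)]]]
          )
        } else {
          ok <- FALSE
          break
        }
      }
      if (ok) break
      n_regenerated <- n_regenerated + 1L
    }

    root <- if (domain == "melody") target$root else NA_integer_
    for (referent in c(FALSE, TRUE)) {
      rows[[length(rows) + 1L]] <- data.frame(
        domain = domain, target_id = tid, variant = "target",
        manipulation_size = "none", manipulation_sign = "none",
        manipulation_position = NA_integer_, manipulation_delta = NA_integer_,
        contour_class = "n/a", referent = referent, root = root,
        pattern = pattern_to_string(target)
      )
      for (m in seq_len(nrow(palette))) {
        for (cls in c("changed", "unchanged")) {
          v <- picks[[m]][[cls]]
          pos <- variant_position(target, v, domain)
          rows[[length(rows) + 1L]] <- data.frame(
            domain = domain, target_id = tid, variant = "manipulated",
            manipulation_size = palette$manipulation_size[m],
            manipulation_sign = palette$manipulation_sign[m],
            manipulation_position = pos,
            manipulation_delta = palette$delta[m],
            contour_class = cls, referent = referent, root = root,
            pattern = pattern_to_string(v)
          )
        }
      }
    }
  }
  if (n_regenerated > 0L) {
    message("regenerated ", n_regenerated,
            " target(s) lacking a contour-changed or unchanged variant")
  }
  set <- do.call(rbind, rows)
  set$stimulus_id <- sprintf(
    "%s-t%02d-%s%s%s-%s", set$domain, set$target_id,
    ifelse(set$variant == "target", "target",
           paste0(set$manipulation_size, set$manipulation_sign)),
    ifelse(set$variant == "target", "", "-"),
    ifelse(set$variant == "target", "", substr(set$contour_class, 1L, 3L)),
    ifelse(set$referent, "ref", "noref")
  )
  set <- set[, c("stimulus_id", setdiff(names(set), "stimulus_id"))]
  if (classify) {
    set <- classify_framework(set, phase_mode = phase_mode,
                              threshold = threshold)
  } else {
    set$framework_class <- "n/a"
  }
  rownames(set) <- NULL
  set
}

# recover the manipulated interval position by diffing against the target
variant_position <- function(target, variant, domain) {
  if (domain == "rhythm") {
    which(target$intervals != variant$intervals)[1L]
  } else {
    which(target$pitches != variant$pitches)[1L] - 1L
  }
}

#' Construct a single stimulus object
#'
#' Bundles a pattern with its provenance so it can be written to MIDI or
#' audio. [manifest_stimulus()] materialises one manifest row back into this
#' form.
#'
#' @param pattern A pattern object.
#' @param referent Does the stimulus include the referent stream?
#' @param ... Further provenance fields (target_id, variant, contour_class,
#'   ...), stored as-is.
#' @return An object of class `stimulus`.
#' @export
stimulus_record <- function(pattern, referent = FALSE, ...) {
  structure(list(pattern = pattern, referent = isTRUE(referent), ...),
            class = "stimulus")
}

#' @rdname stimulus_record
#' @param manifest A stimulus manifest data frame.
#' @param i Row index or `stimulus_id`.
#' @export
manifest_stimulus <- function(manifest, i) {
  if (is.character(i)) i <- match(i, manifest$stimulus_id)
  row <- manifest[i, ]
  pattern <- string_to_pattern(row$pattern, row$domain, root = row$root)
  stimulus_record(pattern, referent = row$referent,
                  stimulus_id = row$stimulus_id, target_id = row$target_id,
                  variant = row$variant, contour_class = row$contour_class)
}
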