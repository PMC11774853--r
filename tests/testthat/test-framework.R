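test_that("metrical weights follow the binary subdivision hierarchy", {
  w <- metrical_weights()
  expect_length(w, 32L)
  expect_equal(w[0 + 1], 0L)                      # downbeat
  expect_equal(w[16 + 1], -1L)                    # half
  expect_equal(w[c(8, 24) + 1], c(-2L, -2L))      # quarters
  expect_equal(w[4 + 1], -3L)                     # 8th
  expect_equal(w[2 + 1], -4L)                     # 16th
  expect_equal(w[1 + 1], -5L)                     # 32nd
  expect_equal(sum(w == 0L), 1L)
  # coarser positions never weigh less than finer ones
  expect_true(all(w[c(0, 16, 8, 24) + 1] >= max(w[seq(2, 32, by = 2)])))
})

test_that("hand-worked LHL cases score as expected", {
  # on-the-beat quarters: no rest outweighs its note
  expect_equal(lhl_fr_score(rhythm_pattern(c(8, 8, 8, 8))), 0L)
  expect_equal(lhl_fr_score(rhythm_pattern(c(8, 8, 8))), 0L)
  # single onset on the 8th-note pickup to beat 3, sounding into silence:
  # rest weight (beat 3) - note weight (8th) = (-1) - (-3) = 2
  w <- metrical_weights()
  expect_equal(rhythmelody:::lhl_score_onsets(12L, 32L, w), 2L)
  expect_equal(oracle_lhl_onsets(12L, 32L, w), 2L)
  # a downbeat offset by a 32nd is strongly syncopated: the -5 position
  # sounds through the loud positions it vacated, (-1) - (-5) = 4
  expect_equal(rhythmelody:::lhl_score_onsets(1L, 32L, w), 4L)
  expect_equal(oracle_lhl_onsets(1L, 32L, w), 4L)
  expect_error(lhl_fr_score(rhythm_pattern(c(8, 8)), shift_ticks = 3),
               "16th")
})

test_that("span-based scorer agrees with the brute-force silent-tick oracle", {
  set.seed(61)
  shifts <- seq(0L, 30L, by = 2L)
  for (i in 1:250) {
    p <- random_rhythm()
    s <- shifts[sample.int(16L, 1)]
    expect_identical(lhl_fr_score(p, s), as.integer(oracle_lhl(p, s)))
  }
})

test_that("min_syncopation scans all 16 shifts and bounds every score", {
  r <- min_syncopation(rhythm_pattern(c(8, 8, 8, 8)))
  expect_equal(r$min_score, 0L)
  expect_equal(r$min_shift, 0L)
  expect_length(r$score_by_shift, 16L)
  set.seed(62)
  for (i in 1:40) {
    p <- random_rhythm()
    res <- min_syncopation(p)
    expect_true(all(res$score_by_shift >= 0L))
    expect_equal(res$min_score, min(res$score_by_shift))
    expect_lte(res$min_score, res$phase0_score)
    expect_true(all(res$min_score <= res$score_by_shift))
    # rotating the onsets by one 16th permutes the shift set: same minimum
    onsets <- pattern_onsets(p)
    rotated <- vapply(seq(0L, 30L, by = 2L), function(s) {
      o <- onsets + 2L + s
      rhythmelody:::lhl_score_onsets(
        o, as.integer(32L * ceiling((max(o) + 1L) / 32L)),
        metrical_weights())
    }, integer(1))
    expect_equal(min(rotated), res$min_score)
  }
})

test_that("rhythm framework class thresholds the absolute score difference", {
  t <- rhythm_pattern(c(8, 8, 8, 8))
  expect_equal(rhythm_framework_class(t, t), "in")   # identical: diff 0
  # delaying the measure-2 downbeat event by a 32nd (with compensation)
  v <- apply_manipulation(t, +1, 4)
  d0 <- syncopation_difference(t, v, phase_mode = "always_phase0")
  expect_gte(d0$sync_diff, 4L)
  expect_equal(rhythm_framework_class(t, v, referent = TRUE), "out")
  # the same pair under shift minimisation may resolve to a calmer phase
  dm <- syncopation_difference(t, v, phase_mode = "always_min")
  expect_lte(dm$sync_diff, d0$sync_diff)
  expect_identical(
    rhythm_framework_class(t, v, referent = TRUE, phase_mode = "per_referent"),
    rhythm_framework_class(t, v, phase_mode = "always_phase0")
  )
})

test_that("melody framework class is pentatonic key membership mod octave", {
  t <- melody_pattern(c(60, 62, 64, 67), root = 60)
  variant_with <- function(pitch, at = 3) {
    p <- t$pitches; p[at] <- pitch
    melody_pattern(p, root = 60)
  }
  expect_equal(melody_framework_class(t, variant_with(64 + 12)), "in")
  expect_equal(melody_framework_class(t, variant_with(61)), "out")
  # perfect 4th: diatonic but not pentatonic, hence out
  expect_equal(melody_framework_class(t, variant_with(65)), "out")
  # octave displacement of the changed pitch never flips the class
  set.seed(63)
  for (i in 1:30) {
    tm <- generate_melody_target()
    vm <- apply_manipulation(tm, sample(c(-3, -2, 2, 3), 1), sample(15L, 1))
    cls <- melody_framework_class(tm, vm)
    k <- which(tm$pitches != vm$pitches)
    up <- vm; up$pitches[k] <- up$pitches[k] + 12L
    expect_identical(melody_framework_class(tm, up), cls)
  }
  expect_error(melody_framework_class(t, t), "exactly one pitch")
})

test_that("classify_framework augments the manifest consistently", {
  set.seed(64)
  s <- suppressMessages(build_stimulus_set(4, "rhythm", classify = FALSE))
  s <- classify_framework(s)
  man <- s[s$variant == "manipulated", ]
  expect_true(all(man$framework_class %in% c("in", "out")))
  expect_true(all(man$sync_diff >= 0L & man$sync_diff <= 15L))
  expect_identical(man$framework_class, ifelse(man$sync_diff >= 4, "out", "in"))
  # recomputing one row by hand matches the table
  i <- which(man$sync_diff == max(man$sync_diff))[1]
  tgt_str <- s$pattern[s$variant == "target" &
                       s$target_id == man$target_id[i]][1]
  d <- syncopation_difference(
    string_to_pattern(tgt_str, "rhythm"),
    string_to_pattern(man$pattern[i], "rhythm"),
    referent = man$referent[i], phase_mode = "per_referent")
  expect_equal(d$sync_diff, man$sync_diff[i])
  # melody rows get NA syncopation but a key-membership class
  m <- suppressMessages(build_stimulus_set(3, "melody"))
  mm <- m[m$variant == "manipulated", ]
  expect_true(all(is.na(mm$sync_diff)))
  expect_true(all(mm$framework_class %in% c("in", "out")))
})
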