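test_that("rhythm targets respect the interval palette and span bounds", {
  set.seed(21)
  for (i in 1:200) {
    p <- generate_rhythm_target()
    expect_true(all(p$intervals %in% c(4L, 8L, 12L, 16L)))
    expect_gte(length(p$intervals), 8L)
    expect_lte(length(p$intervals), 12L)
    expect_lte(sum(p$intervals), 96L)          # inside three 4/4 measures
    expect_lte(pattern_span(p), 96L)
  }
})

test_that("melody targets stay on the six pentatonic degrees with legal leaps", {
  set.seed(22)
  degrees <- c(-5L, -3L, 0L, 2L, 4L, 7L)
  expect_length(degrees, 6L)
  for (i in 1:200) {
    m <- generate_melody_target()
    expect_length(m$pitches, 16L)
    expect_gte(m$root, 60L)
    expect_lte(m$root, 71L)
    expect_identical(m$pitches[1], m$root)
    expect_true(all(m$pitches %in% (m$root + degrees)))
    leaps <- abs(diff(m$pitches))
    expect_true(all(leaps >= 2L & leaps <= 12L))  # forbids repeats too
  }
})

test_that("generation is deterministic under a fixed seed", {
  set.seed(99); a <- generate_rhythm_target()
  set.seed(99); b <- generate_rhythm_target()
  expect_identical(a, b)
  s1 <- suppressMessages(build_stimulus_set(3, "melody", seed = 123))
  s2 <- suppressMessages(build_stimulus_set(3, "melody", seed = 123))
  expect_identical(s1, s2)
  # bit-for-bit identical manifests
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_manifest(s1, p1)
  write_manifest(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("manipulation changes one event and compensates the next interval", {
  r <- rhythm_pattern(c(8, 8, 8))
  v <- apply_manipulation(r, -2, 2)
  expect_equal(v$intervals, c(8L, 6L, 10L))
  # onsets after the manipulated pair are untouched
  expect_equal(pattern_onsets(v)[4], pattern_onsets(r)[4])
  m <- melody_pattern(c(60, 62, 64), root = 60)
  vm <- apply_manipulation(m, +2, 1)
  expect_equal(vm$pitches, c(60L, 64L, 64L))
  # last interval: no compensation, span shifts by delta
  vl <- apply_manipulation(r, +2, 3)
  expect_equal(vl$intervals, c(8L, 8L, 10L))
  expect_equal(sum(vl$intervals) - sum(r$intervals), 2L)
  expect_error(apply_manipulation(r, 2, 4), "out of range")
  expect_error(apply_manipulation(rhythm_pattern(c(8, 2, 8)), -2, 2),
               "non-positive")
})

test_that("compensation preserves span and single-pitch difference", {
  set.seed(31)
  for (i in 1:50) {
    t <- generate_rhythm_target()
    pos <- sample(length(t$intervals) - 1L, 1)
    v <- apply_manipulation(t, sample(c(-2, -1, 1, 2), 1), pos)
    expect_equal(sum(v$intervals), sum(t$intervals))
    after <- pattern_onsets(t) > pattern_onsets(t)[pos + 1L]
    expect_equal(pattern_onsets(v)[after], pattern_onsets(t)[after])
    tm <- generate_melody_target()
    vm <- apply_manipulation(tm, sample(c(-3, -2, 2, 3), 1),
                             sample(15L, 1))
    expect_equal(sum(tm$pitches != vm$pitches), 1L)
  }
})

test_that("contour arrows compare successive durations or pitches", {
  expect_equal(compute_contour(rhythm_pattern(c(8, 8, 16))), c("same", "up"))
  expect_equal(compute_contour(melody_pattern(c(60, 64, 62), root = 60)),
               c("up", "down"))
  expect_error(compute_contour(melody_pattern(60, root = 60)), "short")
})

test_that("contour change detection matches the arrow definition", {
  r <- rhythm_pattern(c(8, 8, 8))
  expect_true(contour_changed(r, rhythm_pattern(c(8, 6, 10))))
  expect_false(contour_changed(rhythm_pattern(c(4, 8, 16)),
                               rhythm_pattern(c(4, 6, 18))))
  expect_false(contour_changed(r, r))
  expect_error(contour_changed(r, melody_pattern(c(60, 62), root = 60)),
               "comparable")
})

test_that("contour is invariant under transposition and tempo scaling", {
  set.seed(41)
  for (i in 1:30) {
    t <- generate_melody_target()
    v <- apply_manipulation(t, sample(c(-3, -2, 2, 3), 1), sample(15L, 1))
    shift <- sample(-12:12, 1)
    t2 <- melody_pattern(t$pitches + shift, root = t$root + shift)
    v2 <- melody_pattern(v$pitches + shift, root = v$root + shift)
    expect_identical(contour_changed(t, v), contour_changed(t2, v2))
    r <- generate_rhythm_target()
    rv <- apply_manipulation(r, sample(c(-2, 2), 1),
                             sample(length(r$intervals) - 1L, 1))
    r2 <- rhythm_pattern(r$intervals * 2L)
    rv2 <- rhythm_pattern(rv$intervals * 2L)
    expect_identical(contour_changed(r, rv), contour_changed(r2, rv2))
  }
})

test_that("stimulus sets have the full balanced structure", {
  set.seed(51)
  s <- suppressMessages(build_stimulus_set(4, "rhythm"))
  expect_equal(nrow(s), 4 * 18)
  counts <- table(s$target_id, s$referent)
  expect_true(all(counts == 9))
  # per target x referent: 1 target + 4 types x 2 contour classes
  for (tid in 1:4) {
    sub <- s[s$target_id == tid & !s$referent, ]
    expect_equal(sum(sub$variant == "target"), 1L)
    man <- sub[sub$variant == "manipulated", ]
    key <- paste(man$manipulation_size, man$manipulation_sign,
                 man$contour_class)
    expect_equal(length(unique(key)), 8L)
    # every manipulated record differs from its target in one event
    tgt <- string_to_pattern(sub$pattern[sub$variant == "target"], "rhythm")
    for (i in seq_len(nrow(man))) {
      v <- string_to_pattern(man$pattern[i], "rhythm")
      expect_equal(sum(v$intervals != tgt$intervals),
                   if (man$manipulation_position[i] ==
                       length(tgt$intervals)) 1L else 2L)
      expect_identical(
        contour_changed(tgt, v),
        man$contour_class[i] == "changed"
      )
    }
  }
  # target rows carry no manipulation metadata
  tr <- s[s$variant == "target", ]
  expect_true(all(tr$manipulation_size == "none"))
  expect_true(all(tr$contour_class == "n/a"))
  expect_true(all(tr$framework_class == "n/a"))
})
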