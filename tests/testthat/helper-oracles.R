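# Independent oracles used across the suite.

# Brute-force LHL scorer: walks every silent tick of the frame, assigns it
# to the preceding onset, keeps the loudest rest per onset, then sums the
# non-negative (rest - note) weight differences. Deliberately written as a
# per-tick loop, independent of the package's span-based implementation.
oracle_lhl_onsets <- function(onsets, frame_end, weights = metrical_weights()) {
  w_of <- function(t) weights[t %% length(weights) + 1L]
  loudest_rest <- rep(-Inf, length(onsets))
  for (t in setdiff(0:(frame_end - 1L), onsets)) {
    pre <- which(onsets < t)
    if (length(pre) == 0L) next
    i <- max(pre)
    loudest_rest[i] <- max(loudest_rest[i], w_of(t))
  }
  total <- 0L
  for (i in seq_along(onsets)) {
    if (is.finite(loudest_rest[i]) && loudest_rest[i] >= w_of(onsets[i])) {
      total <- total + loudest_rest[i] - w_of(onsets[i])
    }
  }
  total
}

oracle_lhl <- function(pattern, shift_ticks = 0L) {
  onsets <- pattern_onsets(pattern) + as.integer(shift_ticks)
  frame_end <- as.integer(32L * ceiling((max(onsets) + 1L) / 32L))
  oracle_lhl_onsets(onsets, frame_end)
}

# random quantised rhythm patterns, not restricted to the target palette,
# for property-style checks
random_rhythm <- function() {
  rhythm_pattern(sample(1:18, sample(3:12, 1), replace = TRUE))
}

# Closed-form OLS via the normal equations, independent of lm().
oracle_ols <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- nrow(X)
  p <- ncol(X) - 1L
  r2 <- 1 - rss / tss
  list(beta = drop(beta), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

# model matrix for d_melody ~ d_rhythm * framework_side, by hand
perf_model_matrix <- function(perf) {
  out <- as.numeric(perf$framework_side == "out")
  cbind(1, perf$d_rhythm, out, perf$d_rhythm * out)
}

# a fixed condition-performance table with a known generating model
fixed_perf_acceptance <- function(seed, n_per_side = 8L) {
  set.seed(seed)
  perf <- data.frame(
    condition = rep(paste0("c", seq_len(n_per_side)), 2),
    framework_side = rep(c("in", "out"), each = n_per_side),
    d_rhythm = rnorm(2 * n_per_side, 1.5, 0.6)
  )
  perf$d_melody <- 0.2 + 0.5 * perf$d_rhythm +
    0.3 * (perf$framework_side == "out") * perf$d_rhythm +
    rnorm(nrow(perf), 0, 0.2)
  perf
}

# a bare-bones single-cell design for closed-form observer checks
flat_design <- function(n, truth = "different") {
  data.frame(participant = 1L, trained = FALSE, domain = "rhythm",
             truth = truth, referent = FALSE, contour_class = "changed",
             manipulation_size = "small", framework_class = "in")[rep(1, n), ]
}

# minimal two-domain manifest reused (and cached) by several files
.stim_cache <- new.env(parent = emptyenv())
tiny_stimuli <- function(seed = 101, n_targets = 8L) {
  key <- paste(seed, n_targets)
  if (is.null(.stim_cache[[key]])) {
    set.seed(seed)
    .stim_cache[[key]] <- suppressMessages(
      rbind(build_stimulus_set(n_targets, "rhythm"),
            build_stimulus_set(n_targets, "melody"))
    )
  }
  .stim_cache[[key]]
}
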