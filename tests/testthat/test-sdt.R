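make_trials <- function(truth, response, ...) {
  data.frame(truth = truth, response = response, ...)
}

test_that("pooled counts split hits and false alarms by truth", {
  tr <- make_trials(rep(c("same", "different"), each = 10),
                    rep("different", 20))
  res <- pool_counts(tr)
  expect_equal(res$hits, 10L)
  expect_equal(res$false_alarms, 10L)
  expect_equal(res$n_same, 10L)
  expect_equal(res$n_diff, 10L)
  # row order is irrelevant
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(pool_counts(perm), res)
})

test_that("participant-by-domain pooling recovers the design arithmetic", {
  stimuli <- tiny_stimuli(104, n_targets = 16L)
  trials <- simulate_experiment(n_participants = 5, stimuli = stimuli,
                                seed = 15)
  res <- pool_counts(trials, c("participant", "domain"))
  expect_equal(nrow(res), 10L)                 # 2 cells per participant
  expect_true(all(res$n_same == 16L))
  expect_true(all(res$n_diff == 16L))
})

test_that("grouping on different-only factors pools same trials across them", {
  stimuli <- tiny_stimuli(104, n_targets = 16L)
  trials <- simulate_experiment(n_participants = 3, stimuli = stimuli,
                                seed = 16)
  res <- pool_counts(trials, c("domain", "framework_class"))
  # framework is undefined on same trials: both cells of a domain share the
  # full same-trial pool
  for (dom in c("rhythm", "melody")) {
    sub <- res[res$domain == dom, ]
    expect_true(all(sub$n_same == sum(trials$truth == "same" &
                                      trials$domain == dom)))
    expect_equal(sum(sub$n_diff), sum(trials$truth == "different" &
                                      trials$domain == dom))
  }
  # referent is defined on same trials, so it partitions them
  res_r <- pool_counts(trials, c("domain", "referent"))
  expect_true(all(res_r$n_same == 24L))        # 3 x 16 / 2
})

test_that("only asymptotic counts are corrected, and rates stay inside (0,1)", {
  expect_equal(correct_rates(16, 16, 0, 16),
               list(H = 15.5 / 16, F = 0.5 / 16))
  expect_equal(correct_rates(16, 16, 0, 16)$H, 0.96875)
  expect_equal(correct_rates(8, 16, 4, 16), list(H = 0.5, F = 0.25))
  # every possible count maps strictly inside (0, 1)
  for (n in c(1L, 7L, 16L)) {
    r <- correct_rates(0:n, n, 0:n, n)
    expect_true(all(r$H > 0 & r$H < 1))
    expect_true(all(r$F > 0 & r$F < 1))
  }
})

test_that("d-prime and bias match their closed forms and symmetries", {
  H <- pnorm(0.5); F <- pnorm(-0.5)
  expect_equal(dprime(H, F), 2)                # z-difference 1, scale 2
  expect_equal(c_bias(H, F), 0)
  expect_equal(dprime(0.3, 0.3), 0)
  expect_equal(dprime(H, F, scale = "sqrt2"), sqrt(2))
  expect_equal(dprime(H, F, scale = 1), 1)
  # antisymmetry under swapping H and F; criterion flips under complement
  expect_equal(dprime(F, H), -dprime(H, F))
  expect_equal(c_bias(1 - F, 1 - H), -c_bias(H, F))
  expect_error(dprime(1, 0.5), "H")
})

test_that("percentage correct equals its algebraic identity on every cell", {
  stimuli <- tiny_stimuli(104, n_targets = 16L)
  trials <- simulate_experiment(n_participants = 4, stimuli = stimuli,
                                seed = 17)
  res <- sdt_analysis(trials, c("domain", "referent"))
  manual <- (res$H * res$n_diff + (1 - res$F) * res$n_same) /
    (res$n_same + res$n_diff)
  # identity holds exactly when no cell needed extreme-count correction
  uncorrected <- res$hits > 0 & res$hits < res$n_diff &
    res$false_alarms > 0 & res$false_alarms < res$n_same
  expect_equal(res$pct_correct[uncorrected], manual[uncorrected])
  pc <- percent_correct(trials, c("domain", "referent"))
  expect_equal(pc$pct_correct, res$pct_correct)
  # the null observer sits at chance
  null_trials <- simulate_responses(
    rbind(flat_design(4000), flat_design(4000, truth = "same")),
    observer_params(delta = 0, criterion = 0), seed = 18)
  expect_lt(abs(percent_correct(null_trials)$pct_correct - 0.5),
            3 * sqrt(0.25 / 8000))   # 3 binomial SEs of chance

})

test_that("pooled d-prime and bias recover the generating observer", {
  # delta = 0.5, k = 0.5 over 60 participants: d' estimates scale x delta,
  # c estimates k - delta / 2
  stimuli <- tiny_stimuli(105, n_targets = 16L)
  params <- observer_params(delta = 0.5, criterion = 0.5)
  trials <- simulate_experiment(n_participants = 60, params = params,
                                stimuli = stimuli, seed = 19)
  res <- sdt_analysis(trials, grouping = character(0))
  n <- res$n_diff
  # delta-method Monte-Carlo SEs of the probit-transformed rates
  se_z <- function(p, n) sqrt(p * (1 - p) / n) / dnorm(qnorm(p))
  H0 <- pnorm(0.5 - 0.5)        # expected hit rate 1 - pnorm(k - delta)
  F0 <- pnorm(-0.5)
  se_d <- 2 * sqrt(se_z(H0, res$n_diff)^2 + se_z(F0, res$n_same)^2)
  se_c <- 0.5 * sqrt(se_z(H0, res$n_diff)^2 + se_z(F0, res$n_same)^2)
  expect_lt(abs(res$d_prime - 2 * 0.5), 3 * se_d)
  expect_lt(abs(res$c_bias - (0.5 - 0.5 / 2)), 3 * se_c)
})
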