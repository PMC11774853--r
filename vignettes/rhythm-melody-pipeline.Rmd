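---
title: "Methods: stimulus generation, framework scoring and signal-detection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus generation, framework scoring and signal-detection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmelody)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the design choices made where
the design was genuinely open.

## The paradigm

A same/different ("reminder") trial presents a reference pattern followed
by a comparison that is either identical or differs in a single event. Two
domains are probed with structurally parallel stimuli: snare-drum rhythms
(relative timing) and piano melodies (relative pitch). Two factors
manipulate the *relative* structure available to the listener:

* **Contour** — whether the change flips any local up/down/same relation
  between successive inter-onset intervals (rhythm) or pitches (melody).
* **Framework** — whether the change violates the expectation grid the
  pattern implies: the 4/4 metre for rhythm, the major-pentatonic key for
  melody. A **referent** stream (bass drum on every downbeat; a root drone
  one octave down) can reinforce that grid.

## Time representation

All symbolic time lives on an integer grid of 8 ticks per quarter note at
160 BPM in 4/4, so one tick is a 32nd note (46.875 ms), a 16th note is 2
ticks, and a measure is 32 ticks. The smallest manipulation used anywhere
(±1 tick) is therefore exact, and no floating-point time exists upstream of
audio rendering. Patterns are inter-onset interval vectors (rhythm, first
onset pinned to tick 0) or pitch vectors of back-to-back 8th notes
(melody).

## Target generation

`generate_rhythm_target()` draws intervals uniformly from {4, 8, 12, 16}
ticks, sequentially. The constraint stated for the stimuli is only a bound
— 8 to 12 intervals inside three measures — not a sampling procedure, so a
procedure had to be fixed: a draw that would place the final onset outside
the third measure is redrawn from the still-feasible durations; generation
stops when nothing fits or 12 intervals are reached; attempts with fewer
than 8 intervals are discarded wholesale. "Inside three measures" is read
strictly (final onset before tick 96), so the last event still sounds
within the three-measure frame; with 4-tick multiples this caps the
interval sum at 92 ticks. The redraw-from-feasible rule biases the tail of
a pattern toward shorter intervals, which is what makes 12-interval targets
reasonably common; the interval-count ceiling of 12 is structural, never
exceeded.

`generate_melody_target()` draws a root uniformly from MIDI 60–71 and
pitches from the six pentatonic degrees {−5, −3, 0, +2, +4, +7} semitones
around it, first pitch pinned to the root, each leap constrained to 2–12
semitones in absolute size. The leap rule is read as a constraint on
consecutive-note intervals; since the degree set spans exactly −5..+7, 12
is the attainable maximum, and the minimum of 2 forbids repeats (no degree
pair is 1 semitone apart, so that case is vacuous). Every degree has at
least one legal successor — from the root, five — so sampling never
dead-ends.

## Manipulations, compensation and contour

`apply_manipulation(pattern, delta, position)` changes the interval at
`position` by `delta` (rhythm: ±1 or ±2 ticks; melody: ±2 or ±3 semitones)
and the next interval by `−delta`. Exactly one event moves; all later
onsets (and for melody, all other pitches) are untouched. At the last
interval there is nothing to compensate and the span changes by `delta`.
Legal targets keep manipulated rhythm intervals in [2, 18] ticks, so the
positivity assertion cannot fire for generated stimuli. Melody
manipulations may leave the pentatonic set and (in principle) the octave
range — both are permitted; the first is the point of the framework factor.

Contour is the vector of up/down/same arrows between successive elements.
`contour_changed()` is any arrow-wise difference. `build_stimulus_set()`
enumerates each manipulation type at every position, classifies each
candidate, and draws one contour-changed and one contour-unchanged variant
per type uniformly among the eligible positions. A target for which some
type has no eligible position in one class is regenerated rather than
relaxing the 4 × 2 balance; with the palettes above this affects a minority
of targets (a message reports the count). Manipulation sign is recorded in
the manifest but not balanced within the changed/unchanged draw — nothing
in the design requires it, and the sign marginal stays close to even by
symmetry of the candidate pool.

## Syncopation and the framework split

The rhythm framework score is the Longuet-Higgins & Lee metric as
operationalised by Fitch & Rosenfeld. The metrical weight of a tick comes
from the binary subdivision tree of one measure: 0 for the downbeat, −1 for
the half, −2 quarters, −3 8ths, −4 16ths, −5 32nds (`metrical_weights()`).
Only weight *differences* matter downstream, so the anchoring at 0 is a
convention. Each sounded note is paired with the loudest silent tick
strictly between it and the next onset (the final note's rest runs to the
end of the measure frame containing it); a pair contributes
`w_rest − w_note` when that is non-negative. The score is a sum of
non-negative terms, and zero for any pattern in which no note sounds
through a stronger silent position — on-beat isochrony scores 0. An
independent brute-force scorer that walks every silent tick is kept in the
test suite and agrees with the span-based implementation on a thousand
random patterns per run.

Because an unaccompanied rhythm does not pin down the metre, listeners can
reinterpret a highly syncopated pattern in a calmer phase:
`min_syncopation()` therefore evaluates the score at all 16 shifts of one
16th note and keeps the minimum (ties to the smallest shift). The framework
class of a variant is `out` when the absolute score difference to its
target reaches 4 — the magnitude of a downbeat displaced by a 32nd note.
Three open choices are resolved as follows and exposed as switches:

* **Which phase enters the published split** is ambiguous when a referent
  enforces the metre. Default `per_referent`: referent stimuli are scored
  at phase 0, non-referent stimuli at the shift minimum
  (`always_min`/`always_phase0` are available).
* **Signed vs absolute difference**: absolute, consistent with a
  non-negative published range.
* **Threshold comparison** is `≥ 4`.

Under this convention a single compensated manipulation moves the score by
at most a few units (empirically ≤ 7 across full sets; two note–rest pairs
change, each bounded by the 0..−5 weight span), and roughly 10% of selected
variants classify as out-of-framework rather than an even split. The
balanced split reported for the original stimulus set evidently reflects a
different (unpublished) scoring convention or target sample; the threshold
and the hand-checkable examples are reproduced as stated, so the convention
here is kept and the discrepancy documented rather than tuned away.

Melody framework is simpler: the changed note is out-of-framework iff its
pitch class relative to the root (mod 12, so octave displacement never
matters) leaves {0, 2, 4, 7, 9}. Note that ±3 around the major second
yields the perfect fourth and major seventh — diatonic but not pentatonic,
hence out.

## The synthetic observer

`build_design()` lays out, per participant, one rhythm and one melody block
(order random) of 32 trials: each target once as same and once as
different; referent on half the trials balanced within truth level;
contour-changed/unchanged balanced 8/8 among different trials (4/4 within
each referent half). The manipulation type actually shown is drawn
uniformly among the variants matching the trial's cell, mirroring an
experiment that randomises manipulation size at run time.

`simulate_responses()` implements the simplest observer whose pooled-d′
estimand is known exactly: evidence X ~ N(0, 1) on same trials,
N(δ_cell, 1) on different trials, response "different" iff X > k. Expected
rates are F = 1 − Φ(k) and H = 1 − Φ(k − δ), so pooled d′ at scale `s`
estimates `s·δ` and c estimates `k − δ/2` — the closed forms the test suite
checks at n = 10,000 and in a 60-participant recovery run (δ = 0.5,
k = 0.5, agreement within 3 delta-method Monte-Carlo SEs).

`default_observer_params()` mirrors the qualitative human pattern rather
than any fitted values: in-key melody changes undetectable (δ = 0, which
reproduces below-chance "different" accuracy after response bias),
out-of-key changes detectable and size-sensitive (0.7 small / 1.3 large),
rhythm changes detectable in-framework (1.1) but hard when small and
out-of-framework (0.4), a +0.2 bump from the rhythm referent, a criterion
of 0.5 favouring "same", and a +0.5 training boost confined to out-of-key
melody cells. These are scaffolding constants for exercising the analysis,
not estimates of human parameters.

What the simulation deliberately omits: memory decay over the 2 s retention
interval, attention lapses, sequential effects, any acoustic front end, and
item-level difficulty beyond the condition cell. Passing recovery tests
therefore validates the estimators and the design bookkeeping — not any
claim about human listeners.

## Signal-detection estimators

`pool_counts()` pools over participants within cells. Grouping variables
that are undefined on same trials (framework, contour, size — properties of
a manipulation) partition only the different trials; the false-alarm pool
is then matched on the remaining variables (participant, domain, referent,
...). This is the natural reading of pooled per-factor d′ in this design,
where a same trial has no framework class.

`correct_rates()` adjusts only asymptotic counts — 0 → 0.5 and
n → n − 0.5 before dividing — leaving all other counts untouched (the
literal reading of the stated rule; not the log-linear
correct-everything variant). Corrected rates are strictly inside (0, 1)
for every possible count.

`dprime(H, F, scale = 2)` uses a literal multiplicative factor of 2 as the
reminder-design transform, following the source analyses; users who prefer
the √2 differencing-model convention can pass `scale = "sqrt2"` (any
number works). `c_bias` is −(z(H) + z(F))/2, positive when "same" is
favoured. Percentage correct is reported untransformed and equals
`(H·n_diff + (1 − F)·n_same) / (n_same + n_diff)` whenever no correction
fired.

Inferential fits beyond this (Gaussian GLMs on d′, binomial GLMMs on
accuracy, marginal-means contrasts) are intentionally not wrapped: the
trial and cell tables are plain data frames in exactly the shape `stats`,
`lme4` or `emmeans` accept, and coefficient replication would require the
original human data.

## Cross-domain regression

`condition_performance()` computes pooled d′ per framework side per
condition and pairs the two domains; `grouped_regression()` fits
`d_melody ~ d_rhythm * framework_side` by OLS (`lm`), reporting
coefficients, the out-of-framework simple slope, adjusted R²
(1 − (1−R²)(n−1)/(n−p−1)) and standard p-values. Because the exact set of
condition cells behind the published grouped analysis is not enumerated,
both constructions are exposed: `cells = "marginal"` (one row per factor
level per side, factors analysed separately) and `cells = "crossed"`
(referent × contour × size jointly). `participant_performance()` +
`individual_regression()` give the individual-level variant with training
and framework-side covariates; zero residual variance (identical
participants) is flagged with a warning rather than an error.

The suite verifies the fit against a hand-rolled normal-equations solver to
1e-10 and checks a qualitative recovery property: when an observer gives
melody and rhythm a *shared* sensitivity perturbation across
out-of-framework cells only (`shared_sensitivity_params()`), the fitted
out-of-framework slope is positive in at least 90% of 50 seeds. Sizing that
check honestly requires a power argument: with 60 participants, the rare
(~10%) out-of-framework rhythm cells pool only about a dozen different
trials each, putting the measurement SE of a per-cell pooled d′ near 0.8.
The shared component must dominate that noise, so its SD defaults to 0.6
(slope z ≈ 3.4 under the delta-method calculation), with 0.1 of
domain-specific cell noise. At σ_shared → 0 the property disappears, as it
should.

## Numerical and I/O choices

* All scores, ticks and pitches are integers end to end; the only floating
  point is in rates, d′ and audio.
* Determinism: every generator accepts a seed; a fixed seed reproduces a
  stimulus set bit-for-bit through the manifest writer.
* MIDI: format 0, division 8 (the grid's ticks-per-quarter), tempo
  meta-event 375,000 µs per quarter; snare on percussion key 37, bass-drum
  referent on key 36, melody on channel 1 with program 1. A minimal reader
  supports round-trip verification of onsets and pitches.
* WAV: mono 16-bit PCM. Voices are deterministic oscillators (two-partial
  decaying burst for snare, low decaying sine for the bass drum, plain
  sines for melody notes) — timbre is irrelevant to every computation in
  the package, so nothing fancier is warranted. The melody drone is a sine
  one octave below the root, one measure long per measure, linear fades of
  1/20 of its duration on each side, mixed at −15 dB relative to pattern
  events; its phase starts at 0 (unstated in the source, fixed here as a
  documented default).
* Pattern spans are rounded up to whole measures so referent streams tile
  them exactly.

## Problem sizes in the shipped tests

The suite runs the structural checks at full experimental scale (16
targets, 288 records per domain), oracle equivalence on 1,000 random
patterns, closed-form observer checks at n = 10,000 trials, the recovery
checks at 60 simulated participants, and the slope-recovery property over
50 seeds of a 60-participant experiment — a few minutes in total, chosen so
the full-scale design is exercised rather than a miniature.

## Known limitations

* The framework split under this scoring convention is ~90/10, not
  balanced; analyses grouping on rhythm framework inherit small
  out-of-framework cell counts.
* The observer has no item, sequence or time-on-task structure; its
  parameter table is per condition cell only.
* Only the major pentatonic scale and 4/4 metre ship; the scale table and
  weight tree are the extension points.
* Audio is for inspection and archiving, not psychoacoustic fidelity.
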