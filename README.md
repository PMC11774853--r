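# rhythmelody

Tools for building and analysing same/different experiments on *relative*
perception of rhythm and melody — the ability to recognise a pattern by its
internal interval relations regardless of absolute tempo or pitch. The
package is aimed at auditory-cognition and music-psychophysics researchers
who need (a) constrained random stimulus sets whose manipulations are
classified by contour impact and by framework conformity (metre for rhythm,
key for melody), and (b) a signal-detection analysis of the resulting trial
tables, with a synthetic observer so the whole pipeline is testable end to
end before any participant is run.

## What it computes

**Stimuli.** Rhythm targets are sequences of 8–12 inter-onset intervals
drawn from {8th, quarter, dotted-quarter, half} notes on a 32nd-note tick
grid (8 ticks per quarter, 4/4, 160 BPM), fitting inside three measures.
Melody targets are 16 eighth notes on the major pentatonic degrees
{−5, −3, 0, +2, +4, +7} semitones around a root drawn from MIDI 60–71, with
consecutive leaps of 2–12 semitones. Each manipulation changes a single
event (±1 or ±2 ticks; ±2 or ±3 semitones) and compensates the following
interval so everything downstream is untouched; per manipulation type, one
contour-changing and one contour-preserving variant enter the set:
4 types × 2 contour impacts + the target = 9 stimuli per target, with and
without a referent (bass drum on every downbeat, or a root drone one octave
down) = 18, so 16 targets give 288 records per domain. Stimuli can be
written to Standard MIDI Files, rendered WAV, and a manifest CSV.

**Framework scoring.** Rhythm variants are scored with the
Longuet-Higgins & Lee syncopation metric in the Fitch & Rosenfeld
formulation: metrical weights 0 (downbeat) to −5 (32nd positions) from the
binary subdivision tree, each note paired with the loudest silent position
in the rest that follows it, contributing `w_rest − w_note` when
non-negative. Because an unaccompanied rhythm does not enforce a metre, the
score is minimised over all 16 sixteenth-note phase shifts; a
target-vs-variant difference ≥ 4 is out-of-framework. Melody variants are
out-of-framework when the changed note leaves the root's major pentatonic
scale (pitch class ∉ {0, 2, 4, 7, 9}).

**Analysis.** Hits (different trials answered "different") and false alarms
(same trials answered "different") are pooled over participants per
condition cell; counts of 0 or *n* become 0.5 and *n* − 0.5 before the
probit transform; then

    d' = 2 · (z(H) − z(F))        (reminder design; the factor is configurable)
    c  = −(z(H) + z(F)) / 2

plus raw percentage correct. Cross-domain covariation is assessed by OLS of
melody d′ on rhythm d′ with a framework-side interaction, at the condition
level and the participant level.

**Synthetic observer.** An equal-variance Gaussian observer (evidence
N(0, 1) on same trials, N(δ_cell, 1) on different trials, "different" iff
evidence > k) simulates the full balanced design — two 32-trial blocks,
16 same + 16 different, referent and contour balanced — so every estimator
above can be verified against closed forms and parameter-recovery checks.

## Worked example

```r
library(rhythmelody)
stimuli <- rbind(build_stimulus_set(16, "rhythm", seed = 1),
                 build_stimulus_set(16, "melody", seed = 2))
trials <- simulate_experiment(n_participants = 60, stimuli = stimuli, seed = 3)
sdt_analysis(trials, c("domain", "framework_class"))
```

```
  domain framework_class n_diff hits false_alarms d_prime  c_bias pct_correct
1 melody              in    556  165          326   -0.24  0.4737       0.527
2 melody             out    404  316          326    2.39 -0.1830       0.696
3 rhythm              in    837  620          321    2.15 -0.1089       0.701
4 rhythm             out    123   75          321    1.41  0.0746       0.659
```

Under the default observer (which mirrors the qualitative human pattern),
in-key melody changes go essentially undetected — pooled d′ is slightly
negative and accuracy sits near chance — while out-of-key changes and most
rhythm changes are readily detected. The cross-domain regression on the
same table:

```r
fit <- grouped_regression(condition_performance(trials))
fit$coefficients; fit$out_slope; fit$adj_r_squared
```

```
                           Estimate Std. Error t value Pr(>|t|)
(Intercept)                  -0.147      1.334  -0.110    0.914
d_rhythm                     -0.041      0.619  -0.066    0.948
framework_sideout             2.154      1.362   1.582    0.140
d_rhythm:framework_sideout    0.293      0.643   0.456    0.656
out-of-framework simple slope: 0.252   adjusted R^2: 0.969
```

i.e. the condition-level melody–rhythm association, such as it is under
this observer, lives in the out-of-framework conditions.

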