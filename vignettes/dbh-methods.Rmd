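---
title: "Difference-between-hands analysis of piano performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference-between-hands analysis of piano performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pianodbh)
```

`pianodbh` measures how differently a pianist's two hands behave while
playing material that is nominally identical across hands, and uses those
differences to characterise and classify performance proficiency. This
vignette documents the models, the parameter choices and their rationale,
the numerical conventions, and what the synthetic test bed does and does
not establish.

## Why unison exercises

Both built-in excerpts are isochronous unison lines: Hanon Exercise
No. 1 (eighth notes at 120 bpm, right hand from C4, left hand two octaves
below) and a C-major scale over four octaves (sixteenth notes at 60 bpm,
hands one octave apart). At these tempi every note nominally lasts
0.25 s in both excerpts, and the *k*-th right-hand note shares its
notated onset with the *k*-th left-hand note. This design makes the two
hands directly comparable: any timing, duration or loudness difference
between paired notes is performer behaviour, not repertoire.

The published figures of the excerpts are not machine-readable, so
excerpt lengths are configurable. The defaults — seven ascending Hanon
patterns plus their descending mirror (112 notes per hand, 28 s nominal)
and one ascending-descending four-octave scale pass (57 notes per hand,
14.25 s) — were chosen so nominal playing time approximates the
per-performer recording averages implied by the study's total recording
durations. Two conventions are ours: the Hanon descent is the retrograde
of the ascent with patterns transposed diatonically (one C-major scale
step each), and the scale registers are C4/C3 (only the Hanon registers
are documented in the source material).

## Score-performance alignment and hand inference

The original study used an external symbolic alignment tool. Because both
excerpts are monophonic per hand, `pianodbh` instead uses a transparent
order-preserving dynamic program on pitch sequences: match cost 0,
substitution cost 1.0 within ±2 semitones (beyond that a wrong note is
cheaper to explain as one missed plus one extra), gap cost 0.6 for missed
score notes and extra performed notes. Ties prefer match over
substitution over a missed score note over an extra performed note. The
substitution window bounds spurious matches on scalar material; the gap
cost below the substitution cost keeps single-note slips from dragging
neighbours out of position.

Hand inference is a joint alignment: the performed pitch sequence (in
onset order) is aligned against the score with both hands merged, and the
two members of a score-simultaneous pair may be consumed in either order
— necessary because melody lead means the right-hand note can precede or
follow its left-hand partner in time. Each performed note inherits the
hand of its matched score note; unmatched notes are labelled extra and
take the hand of the nearest-pitch score candidate. Onsets and velocities
never enter the cost, so alignment is invariant to global time shifts and
dynamics. On small instances the dynamic program is tested against
exhaustive enumeration of all monotone matchings.

Two consequences for downstream features: substituted (wrong-pitch) notes
still contribute timing and velocity information, while missed and extra
notes contribute nothing; and no inter-onset interval or delta is formed
across the gap a missed note leaves (the spanning pair would divide a
two-note distance by a one-note score duration and silently corrupt the
log-ratios).

## Feature definitions and conventions

Per matched note: `rDuration = ln(d/s)`, `rIOI = ln(IOI/s)`,
`Articulation = ln(d/IOI)`, `Velocity = v`, with *d* the performed
duration, *IOI* the onset distance to the hand's next matched note, *s*
the score duration in seconds at the notated tempo, and *v* the MIDI
velocity. Deltas are first differences along each hand's stream. DBH
features subtract left from right per notated pair: duration difference
and attack deviation in seconds, articulation difference as a log-ratio
difference, velocity difference in MIDI units, plus their deltas. Records
with non-positive performed IOI (onset inversions after alignment) are
dropped with a warning count.

Conventions fixed here, where the source material is silent:

* **Natural logarithms** for every "logarithmic scale" transform; the
  published DBH articulation magnitudes (~0.09) are consistent with
  natural-log differences.
* **The rDuration/rIOI denominator is the score duration at the nominal
  excerpt tempo** (0.25 s here), making `rDuration` an absolute-tempo
  measure while `Articulation` tracks the performer's own tempo.
* **BH statistics average the two hand statistics** — including the SDs —
  rather than pooling notes across hands; pooling would mix the
  between-hand offset into the spread.
* **Sample SDs** use the n−1 denominator; a statistic over fewer than two
  usable records is `NA`.
* On the isochronous excerpts, `Articulation = rDuration − rIOI` per note
  is asserted to 1e-12 in the test suite.

Aggregation yields 64 named values: 48 Basic (`BH_`/`RH_`/`LH_` × 8
features × mean/SD) and 16 DBH. The "all"-excerpt value of each feature
is the element-wise mean of its two excerpt values.

## Statistical protocol

For every Basic feature statistic, a 2×2 split-plot ANOVA with hand as
the within-subject factor and proficiency group between subjects:
between-subject error is subjects-within-groups, within error is
hand-by-subject-within-groups, each effect's partial eta squared is
computed against its own error term, and all F tests have df (1, N−2).
The decomposition is hand-written (it is part of the protocol under
study) and cross-checked in tests against `stats::aov` with an
`Error(subject)` stratum, sum-of-squares conservation, and the algebraic
identity that the interaction F equals the squared pooled t on per-subject
hand differences.

DBH features are compared between groups with the **pooled-variance
(Student) t** — this variant, not Welch, reproduces the published df = 66
and the printed t values from the printed group summaries, which is how
the package pins down the protocol. The t is oriented amateur − expert to
match the printed signs. Bonferroni correction multiplies each p by the
number of comparisons and caps at 1. Cohen's *d* uses the pooled-SD
two-condition form; the normality check is fixed to Shapiro–Wilk and the
variance check to mean-centred Levene (the source names neither variant).
Degenerate inputs (all values identical) report F = 0, p = 1 rather than
0/0.

## Classification

Feature sets: Basic (48 columns), DBH (16), Basic+DBH (64). Each set is
z-scored per column (zero-variance columns pass through as zeros with a
warning), decomposed by PCA (components sorted by explained variance,
signs fixed so each component's largest-magnitude loading is positive),
and classified by a linear SVM with C = 1 under stratified 10-fold
cross-validation, scored by F1 with "expert" as the positive class.
Component counts come from cumulative-variance thresholds (95%, 99%), a
best-score sweep over all k (ties to the smallest k), or fixed counts
(10/20/40; the 16-dimensional DBH set is skipped for 20 and 40). Folds are
dealt round-robin within each class after a seeded shuffle, so fold sizes
differ by at most one per class and every fold contains both classes.

Two deliberate choices: the scaler and PCA are fitted on the whole data
set before cross-validation **by default**, mirroring the protocol as
published even though it leaks test information into the transform
(`fold_safe = TRUE` refits both inside each training fold for a clean
estimate); and the directional comparison between feature sets is
evaluated under the best-score condition, the headline condition of the
published comparison.

## The synthetic cohort generator

The generator is this package's own construction: the study reports only
summary statistics, so the simplest model that reproduces the published
group moments is used, with all distributions normal and truncated at
physical limits. It is two-level:

* **Performer-level traits**, drawn once per performer and persistent
  across excerpts: a multiplicative tempo scalar (mean 1, SD 0.05 expert
  / 0.07 amateur — the study showed the metronome only before playing);
  mean attack asynchrony (expert −0.004 s, amateur +0.0008 s, between-SDs
  0.004/0.005 s); mean right-minus-left duration imbalance (0.021 s vs
  0.009 s, between-SDs 0.013/0.018 s); mean right-minus-left velocity
  offset (11.083 vs 7.521 MIDI units, between-SDs 3.472/2.606); an
  overall loudness shift; and — crucially — each performer's own
  *regularity*: the within-performance SDs of asynchrony, duration noise,
  velocity noise and its note-to-note increments are themselves
  performer-level draws. Without that level, SD-type aggregate features
  are group constants and the classification task degenerates.
* **Note-level rendering**: left-hand onsets follow the tempo-scaled
  score plus AR(1) jitter (coefficient 0.3, giving realistic delta-SD
  structure); each right-hand onset is its partner's onset plus an
  asynchrony draw; durations are per-hand articulation ratios (left-hand
  default 0.88 expert / 0.85 amateur, the right hand offset so the mean
  duration difference hits its target at the nominal IOI) times the
  realized IOI; velocities are a hand base plus a contour term following
  normalized pitch height (gains 8/5 expert RH/LH, 4/4 amateur —
  experts shape the melody hand more) plus autocorrelated noise whose
  marginal SD and increment SD are solved jointly for an AR(1)
  coefficient; wrong (±1–2 semitones), missed and extra notes are
  injected at 0.2% per note for experts and 1% for amateurs. Velocities
  are clipped to [1, 127] and kept real-valued in memory (files round to
  integers on write).

The velocity-noise budget deserves a note: the published note-level DBH
velocity SD absorbs both the contour-gain difference between hands and
the independent per-hand noise, so the per-hand noise SD is
`sqrt((sd_dbh² − gain_diff²)/2)` and the AR(1) coefficient is
`1 − delta_sd²/(4·var_noise)`, clamped into feasibility for extreme
per-performer draws.

**What passing tests show — and what they do not.** The generator
reproduces the published first and second moments of the DBH aggregates
and yields cohorts on which the full pipeline recovers its calibration
targets within Monte-Carlo error. It does not reproduce the correlation
structure of real performers: traits are drawn independently across
features, whereas real skill dimensions correlate. Synthetic cohorts are
therefore *more* linearly separable than the recorded ones (fold F1 near
1 rather than ≈0.87–0.94), which is why the classification claims tested
here are directional (adding DBH features does not hurt, and the DBH set
alone is informative) rather than absolute F1 levels. Real-data features
the generator also omits: pedal effects, fatigue and drift over a
session, serial correlation of errors, and any biomechanical coupling
between hands.

## Numerical choices and degenerate inputs

* Alignment backtrace compares costs with a 1e-9 tolerance (different
  summation orders of the same optimal cost differ by rounding).
* Empty performances are rejected by the hand splitter; empty inputs to
  the per-hand aligner give an all-gap alignment.
* MIDI files are written format 1, one track, 480 ticks per quarter;
  round-trip onset/offset error is at most half a tick. Note-on with
  velocity 0 is read as note-off; overlapping same-pitch notes pair
  first-in-first-out; dangling note-ons raise an error listing pitches.
* Zero pooled variance with unequal means reports a signed infinite t
  with an explicit flag; with equal means, t = 0.
* Generator parameters that imply non-positive performed IOIs raise an
  error rather than clamping silently.

## Problem sizes in the test suite

The suite exercises the full study geometry once — a 34 + 34 cohort on
the full-length excerpts for calibration recovery — and uses reduced
cohorts elsewhere (17 + 17 or 8 + 8 performers, four Hanon patterns,
two scale octaves) where the property under test concerns structure
rather than cohort-level precision: repeated-seed directional
classification, permuted-label chance levels, and hand-assignment
accuracy under elevated error rates. The acceptance script simulates the
34-performer expert cohort on both full excerpts.

## Known limitations

* Polyphony within a hand, ornaments and pedal are out of scope; the
  aligner assumes monophonic per-hand streams.
* The pitch-only alignment cost can in principle mis-pair a wrong note
  with a neighbouring score note on densely chromatic material; on the
  diatonic excerpts the ±2-semitone window makes this rare, and the
  hand-assignment accuracy requirement (≥99% at ≤2% error rates) is part
  of the test suite.
* Published classification F1 values depend on the unavailable human
  recordings and are not reproduction targets; see the generator section
  for what replaces them.
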