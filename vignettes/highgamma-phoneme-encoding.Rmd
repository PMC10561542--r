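---
title: "Analysing phonological encoding in high-gamma ECoG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing phonological encoding in high-gamma ECoG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgspeech)
```

## The scientific problem

During speech production the brain must coordinate phonological units of
very different durations: plosive consonants are distinguished by acoustic
events of tens of milliseconds, vowels last hundreds of milliseconds, and a
whole consonant-vowel-consonant (CVC) syllable spans most of a second. A
long-standing hypothesis holds that the left hemisphere is specialized for
the short units and the right hemisphere for the long ones. Intracranial
recordings (electrocorticography, ECoG) during a CVC repetition task make
this question testable electrode by electrode: high-gamma band power
(70–150 Hz) tracks local population firing, and a decoding analysis can ask
how strongly each recording site carries consonant, vowel, or syllable
identity, when in the trial it does so, and in which hemisphere it sits.

`hgspeech` implements that analysis chain end to end, together with a
synthetic-session generator that plants known temporal response profiles
and phonemic tuning so every stage can be validated against ground truth.

## The task and the stimulus inventory

The simulated task mirrors a paced reading design: a CVC syllable appears
on screen for 1 s and the participant reads it aloud immediately. Twelve
CVCs are built from four initial consonants (b, d, g, j) crossed with three
vowels (ae, i, u), each initial consonant carrying a fixed final consonant
(b–g, g–b, d–j, j–d). Consonant order matters, so `"b-g"` and `"g-b"` are
distinct consonant-pair classes; the decoded label sets are therefore
4 consonant pairs, 3 vowels, and 12 syllables. Only the first word of each
presentation pair is analyzed, one utterance per trial.

## Synthetic sessions

`generate_session()` produces a neural recording, an audio track, a trial
table, and the planted ground truth. The design choices that matter:

* **Reaction times** are truncated normal (mean 900 ms, sd 200 ms,
  truncated at 300 ms so no utterance precedes its stimulus
  non-physically). Trials are spaced by the full pair structure
  (1 s + 1.5 s + 1 s plus a randomized 3–5 s inter-pair gap by default).
* **Temporal response profiles.** Each electrode is assigned one of six
  canonical templates (`canonical_templates()`), piecewise-linear shapes
  parameterized by start, peak and end times and onset/offset slopes,
  spanning speech-preparatory through post-production responses. Two
  templates are right-censored (still elevated 1 s after voice onset).
* **The high-gamma carrier.** Planted responses are implemented as
  amplitude modulation of band-limited (70–150 Hz) noise added to 1/f
  background noise and optional 60 Hz line noise — so the Hilbert
  filter-bank extraction path, not a shortcut, has to recover them.
* **Phonemic tuning** is multiplicative: a tuned electrode's response is
  scaled by (1 + effect) on trials whose consonant-pair / vowel / syllable
  label matches its preferred label. Each electrode is tuned to at most one
  unit, which keeps preference ground truth unambiguous. A per-unit
  `left_bias` controls where tuned electrodes land, so lateralization
  statistics have a planted truth.
* **Audio** is a near-silent background with broadband voicing bursts at
  each voice onset; burst duration is a free parameter (the task design
  does not pin down utterance lengths), 450 ms by default.

`generate_ersp_profiles()` additionally builds trial-averaged ERSP
time-courses directly (template plus noise, averaged over the session's
trial count). An "SNR 3" profile set means single-trial noise sd equal to a
third of the template peak; the averaged profile noise then shrinks with
the square root of the trial count, exactly as a real event-related
average does. This matters: with profile-level (un-averaged) noise at a
third of the peak, within-template pairwise distances under the
exponential distance equal the between-template shape distances, and no
clustering of this family can separate the templates.

What the generator does **not** emulate: cortical geometry and volume
conduction, epileptiform or movement artifacts, coarticulation, any
dependence of the response shape on the spoken content beyond the
multiplicative scaling. Passing tests on synthetic sessions therefore
validate the computational chain, not the biology.

## Signal conditioning

`preprocess_neural()` downsamples to 1 kHz (polyphase antialiasing),
removes each channel's DC over the whole record, applies zero-phase notch
filters at 60/120/180/240 Hz, flags channels whose sample kurtosis exceeds
the channel median + 5 MAD (the bound is a robust default; a manual
override list is honored, mirroring hand-verified channel removal), and
re-references by subtracting each grid's mean over valid channels
(grid-wise common average reference).

`extract_high_gamma()` splits 70–150 Hz into 8 logarithmically spaced
bands (9 log-spaced edges, 4th-order zero-phase Butterworth per band),
takes the magnitude of the analytic signal per band, and averages the
envelopes.

`epoch_and_normalize()` cuts −2000…+1000 ms around each voice onset
(half-open windows; 3000 samples at 1 kHz) and z-scores each
electrode-trial against the 500 ms immediately preceding stimulus onset.
The phrase "first 500 ms before stimulus presentation" admits a second
reading — the earliest 500 ms of the pre-stimulus epoch — which is exposed
as `baseline_mode = "epoch_start"`.

**Responsiveness screening** is two-staged. The confidence-interval screen
asks whether the trial-averaged ERSP ever leaves the 95% band
(mean ± 1.96 sd) of the *single-trial* z-scored baseline activity. Because
z-scoring fixes the single-trial baseline at sd 1 while averaging over
`n` trials shrinks the ERSP noise by √n, this band (≈ ±1.96 z) is crossed
essentially only by genuine task deviations — which is what keeps the
false-positive rate of the screen at the few-percent level rather than the
near-certain exceedance a pointwise band on the averaged trace itself
would produce. The second stage requires the Kalman trend analysis (below)
to report at least one post-baseline change point.

## Kalman trend analysis

The filter tracks the two-dimensional state (power, trend) with the
constant-velocity transition `A = [[1,1],[0,1]]` and observation model
`H = [1, 0]`. Initialization from the baseline: state `[0, 0]`; `Q` from
the variance of the first-differenced baseline (trend component divided by
τ² with τ = 10 samples — the phrase "difference-stationary whitened
variance" under-determines a 2×2 matrix, and a diagonal form is the
conservative completion); `P = Q`; `R` = baseline variance.

The gain is decayed by α = exp(−Δ/(δ·Fs)) with δ = 100 ms, where Δ counts
steps since the last (re-)initialization. This progressively "freezes" the
current trend so that data departing from it produce growing innovations
instead of being absorbed. A change point is recorded when the absolute
innovation |z − HX| exceeds a global threshold; the filter then
re-initializes at the change with the empirical slope fitted over 100 ms
around it (10% past, 90% future), `P` recomputed from the local signal,
and the decay reset. The raw innovation (not a variance-normalized form)
is tested against the threshold, which is expressed in the same z-units.

**Threshold calibration** pools electrodes: each contributes
sd × Φ⁻¹(0.95) of its single-trial z-scored baseline (the Gaussian
upper-tail reading of an "inverse Q-function"); a beta distribution is
fitted to the pooled values by the method of moments (values rescaled to
(0,1) by their maximum; empirical 99% quantile as fallback if the fit
degenerates), and its 99% quantile becomes the single threshold shared by
all electrodes — one global criterion rather than per-electrode tests,
which is the multiple-comparison correction. The analyzed traces are
trial-averaged, so a threshold near 1.7–2 z against averaged noise of
~1/√n z gives per-electrode false-change rates well under 1%.

Landmarks (`extract_landmarks()`): start = first post-baseline change
point; peak = time of maximum |power|; end = first sustained (≥ 50 ms)
return into the baseline 95% band after the peak, reported as
right-censored when the trace is still elevated at the epoch end;
onset/offset slopes are least-squares fits over the rising/falling
segments, in 1/s.

## Clustering of response time-courses

Profiles are min–max normalized to [0, 1] and compared with
`DIST(p, q) = Σᵢ (exp(pᵢ) − exp(qᵢ))²`, which stretches differences at
high-activity time points relative to near-baseline ones. It is a
semi-metric (the triangle inequality is not guaranteed and not used).

`hybrid_cluster()` is agglomerative with a partitioning repair: merge the
closest centroid pair (ties broken by lowest index, so results are
deterministic), recompute the member-mean centroid, and, whenever an
existing cluster sits closer to the new centroid than the just-paid merge
distance (a monotonicity violation), reallocate electrodes among the
merged and violating clusters k-means-style (electrode-to-centroid
distances, iterated to convergence with a 100-sweep cap, never emptying a
cluster). Recorded merge heights are made non-decreasing.

Two criteria pick the cluster count. The *elbow* is the largest second
difference of the **log** merge-height curve over k — the point where the
rate of distance reduction slows most sharply in relative terms. The log
form is deliberate: canonical response families are themselves
hierarchically organized (pre-speech vs peri-speech supergroups), so the
raw-height curvature peaks at the supergroup split even when the tree has
an unambiguous finer plateau; relative curvature recovers the visual
elbow. The *variance* criterion takes the smallest k whose explained
variance (1 − SS_within/SS_total) gains less than 5 percentage points from
k+1. When the two disagree, both are reported and the variance candidate
is used. Clusters are finally renumbered by ascending start landmark of
their centroids.

## Decoding

Features are 50-ms moving averages at 25-ms stride over a ±1 s window
around voice onset — 79 per electrode. Feature selection is greedy mRMR in
the mutual-information-difference form on equal-frequency 8-bin
discretized features, run on training folds only; the top 150 features
across electrodes feed a linear discriminant classifier. The LDA uses a
pooled within-class covariance shrunk toward a scaled identity with an
analytically estimated (Ledoit–Wolf-type) intensity, which keeps the
classifier defined in the 150-features/100-trials regime. Cross-validation
is 5-fold, stratified by syllable label so that all three unit labelings
stay balanced across folds; per-trial correctness vectors are retained.

Per-electrode **encoding strength** is pooled accuracy with all electrodes
minus pooled accuracy with that electrode's features removed (feature
selection re-run, folds held fixed). The top 30% of electrodes by strength
across participants are flagged per unit (ceiling rule; boundary ties
broken by position with a warning). **Cluster-specific windows** replace
the fixed ±1 s window by each cluster's start–end interval, tiled by 79
equal windows with stride half the width (width = L/40 for an interval of
length L), and a paired t-test compares subject-level accuracies between
the two windowings. **Single-electrode decoding** restricts mRMR to an
electrode's own 79 features (top 10) and feeds the bootstrap preference
analysis.

**Phonemic preference (PPI).** For 10,000 bootstrap trial sets (shared
across a subject's electrodes), mean accuracies per unit are ranked across
electrodes within each unit (rank 1 = least accurate) and
PPI(unit) = max(rank_unit − rank_other1, rank_unit − rank_other2). An
electrode prefers a unit when the 5th percentile of its PPI distribution
is above zero; dual significance resolves to the higher mean PPI. A
calibration caveat is documented honestly: because the bootstrap resamples
trials around *fixed* cross-validated correctness vectors, finite-sample
accuracy luck in those vectors is never averaged away, and the max-of-two
rank statistic is positively biased at the null boundary. On statistically
identical electrodes the procedure flags roughly 10% of electrode-unit
pairs rather than the nominal 5%, and about a third of null electrodes
receive some preferred unit. The package implements the procedure as
defined; the accompanying test suite records this liberal null behavior
rather than masking it, and detection of genuinely tuned electrodes (an
amplitude effect three times the noise sd) is reliable once a realistic
number of electrodes per subject (a few dozen) enters the ranking.

**Chance levels** use the exact cumulative binomial tail
P(z) = Σᵢ₌z..n C(n,i)(1/c)ⁱ((c−1)/c)ⁿ⁻ⁱ with no normal approximation. The
chance level is reported as the largest accuracy still consistent with
chance, 100·(z*−1)/n where z* is the smallest count with P(z*) < 0.05;
decoding is above chance exactly when observed accuracy exceeds this
level. For n = 646 pooled trials this gives 27.9% (c = 4), 36.4% (c = 3),
and 10.2% (c = 12).

## Population statistics

Lateralization uses the exact two-tailed binomial test
(minimum-likelihood convention) of a set's left-hemisphere count against
the base-rate left proportion, with Wilson 95% intervals for the plotted
proportions and Benjamini–Hochberg FDR across the three units (the
correction method itself, unspecified in common usage notes, is the
standard BH step-up). Distribution tests are Pearson chi-squares
(independence for tables, goodness-of-fit against supplied null
proportions otherwise; no continuity correction). The width regression
fits per-unit binomial-logistic models of top-encoder counts on cluster
response widths; right-censored widths are closed at the epoch end
(+1000 ms) and flagged; complete separation triggers a ridge-penalized
IRLS refit with a warning. The single-subject analysis normalizes
strengths within each unit by that unit's maximum and fits a two-way
ANOVA (hemisphere × unit) on electrodes as observations, reporting
hemisphere-by-unit interaction coefficients relative to the right
hemisphere.

## Numerical choices and degenerate inputs

* All epoch windows are half-open `[start, end)` in ms relative to voice
  onset; slopes are reported per second.
* Zero-variance baselines error at filter initialization and invalidate
  electrode-trials at epoching (with warnings); constant profiles
  normalize to zero with a warning.
* Closest-pair and top-encoder ties break deterministically (lowest index /
  position) with warnings where a tie is scientifically meaningful.
* Bootstrap, fold assignment, and all generators consume the R RNG only,
  so a single `set.seed()` fixes the entire analysis.

## Problem sizes used in the test suite

The packaged tests run the full chain at deliberately small scale: raw
sessions of 8 electrodes × ~25 trials for the end-to-end path, 120–200
template-built ERSP profiles for cluster recovery (10 seeds), 20-seed
planted-preference simulations with 24 electrodes × 144 trials, and
400-replicate null batteries for the change-point and screening
specificity checks. These sizes were chosen so the statistical assertions
(recovery rates, false-positive ceilings) are tested with meaningful
Monte-Carlo resolution while the suite stays comfortably runnable on a
laptop; the pipeline itself has no intrinsic size limits beyond memory.

## Known limitations

* The synthetic generator's single response-template-per-electrode and
  multiplicative tuning are idealizations; real electrodes mix sources.
* The hybrid clustering repairs monotonicity locally; a global optimum is
  not guaranteed (nor claimed by the method it implements).
* The PPI null calibration is liberal, as discussed above.
* HDF5/WAV interchange is not provided; tabular outputs are plain TSV and
  objects are in-memory R structures.
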