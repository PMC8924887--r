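---
title: "Assessing physical fatigue from heart rate variability and pulse arrival time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing physical fatigue from heart rate variability and pulse arrival time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvfatigue)
```

## The measurement problem

Physical fatigue changes autonomic cardiovascular control in ways that are
measurable with wearable-grade sensors: heart rate (HR) rises, the
time-domain heart-rate-variability (HRV) measures SDNN and RMSSD fall, and
the timing of the peripheral pulse relative to the heartbeat shifts.
`cvfatigue` implements a complete pipeline for turning synchronized ECG and
fingertip pulse-wave recordings from a structured cycle-ergometer session
into a binary assessment — *mildly* versus *significantly* fatigued — for
each subject measured once rested (morning, RS) and once after exhausting
exercise (afternoon, PFS).

The session protocol is fixed: 5 min seated rest, then three 3-min cycling
bouts at 60, 90 and 120 W, each followed by 5 min of seated recovery —
29 min in total (`build_schedule()`).  All analysis happens in fixed
sub-windows of the four non-cycling phases:

* **HRV window**: 2.5–4.5 min into the phase (2 min), inside the slow phase
  of heart-rate recovery, for HR, SDNN and RMSSD;
* **PAT window**: 3–4 min into the phase (1 min) for pulse arrival time,
  with a cuff blood-pressure reading taken in the same section.

Windows are closed–open intervals in seconds; a beat belongs to a window if
its R-peak time falls inside it.  This one rule resolves every boundary
case.

## Signal processing

**R-peaks** are detected with a Hamilton–Tompkins style chain: 8–20 Hz
zero-phase band-pass, absolute first difference, 80-ms moving-window
integration, adaptive dual thresholds with a 200-ms refractory period and
search-back for long gaps.  Detections are refined to the local maximum of
the raw ECG (hill-climbing in ±25 ms steps), so reported times sit on the R
wave.  Every threshold adapts to running signal/noise estimates, making the
detector invariant to uniform gain.

**Pulse feet.**  The pulse-wave onset ("rising front") is not a uniquely
defined fiducial; the package fixes it, by default, as the
intersecting-tangent point — the tangent at maximum upslope intersected
with the horizontal through the preceding local minimum — which is the
standard onset definition in pulse-wave-velocity work and is robust to
amplitude scaling.  `max_slope` and a 10% `fractional_threshold` variant
are selectable for sensitivity analyses.

**Per-beat PAT** is the lag from each R-peak to the earliest detected foot
before the next R-peak, accepted only within 100–500 ms.  Window-level PAT
is the arithmetic mean of accepted per-beat values (median available); it
is then normalized to a reference systolic pressure of 120 mmHg at
1 ms/mmHg.  Because PAT shortens when pressure rises, a measurement taken
at above-reference pressure must be *lengthened* back:
`pat_norm = pat + (sbp - 120)`.  The correction is exactly invertible and
the identity at 120 mmHg.

**NN cleaning** replaces manual beat verification with two logged rules:
absolute bounds (300–2000 ms) and rejection of intervals deviating more
than 30% from the median of their five nearest surviving neighbours.

**RMSSD wording.**  The verbal definition of RMSSD circulating in parts of
the applied literature ("square root of the root mean square of the sum of
all differences") does not describe a standard quantity; the package
implements the standard root mean square of successive differences,
`sqrt(mean(diff(nn)^2))`, and documents the choice rather than silently
matching garbled wording.  SDNN uses the sample (n−1) standard deviation.

## The subparameter grammar

From the four per-phase measures in each state the package derives a named
family: per state the raw phase values (`REST`, `REC1..3`), recovery
aggregates (`AVG`, `MIN`) and recovery-normalized composites
(`N_AVG = REST/AVG`, `N_MIN = REST/MIN`); plus percent between-state
changes (`DIF`) of all eight variants.  That is 96 features
(4 measures × 24).  Missing phases propagate as absent values — never
imputed — and recovery aggregates require all three recoveries.

The *reference screened set* (`reference_feature_set()`, 72 features)
excludes the 24 raw rested-state levels: values measured before any
fatigue was induced are subject baselines and cannot, by construction,
express a fatigue response.  The rested-state normalized composites stay
in, since between-state comparisons are made against them.

Two composites deserve naming because they are the intended product of the
design: `SDNN_DIF_N_AVG`, the percent change between states of resting
SDNN normalized by mean recovery SDNN, and `PAT_PFS_N_MIN`, the
fatigued-state resting PAT divided by the lowest fatigued-state recovery
PAT (a dimensionless ratio).  `DIF` features are expressed in percent, and
`PAT_PFS_N_MIN` is left as a raw ratio.

## Grouping, screening and the classifier

Subjects are labelled from their relative change in countermovement-jump
(CMJ) height — the most objective of the reference measures.  The default
rule is a median split (at-or-below-median change, i.e. losing more jump
height, is `significant`; ties go to `significant`); a fixed threshold is
available, since the underlying cut is a design choice rather than a known
constant.

Every feature is screened by **leave-one-out decision stumps**: for each
held-out subject, a depth-1 tree is fitted on the rest (exhaustive search
over midpoints between consecutive sorted distinct values, minimizing
weighted Gini impurity; threshold ties go to the smaller threshold; leaf
ties predict `significant`) and the held-out subject is predicted.  The n
pooled predictions give an F-score (harmonic mean of precision and recall,
`significant` positive) and accuracy per feature.  Pooling, rather than
per-fold averaging, is forced by fold size 1: per-fold F is undefined.
Features rank by F-score, then accuracy, then name — every tie-break is
deterministic, so screening results are bit-reproducible.

`fatigue_classifier()` then trains a soft-margin linear SVM (cost C,
default 1) on the two top-ranked features.  Because screened features can
differ in scale by orders of magnitude (percent changes versus ratios near
one), the solver standardizes internally; coefficients are back-transformed
and reported on the original feature scale as
`w1*x1 + w2*x2 + b = 0`, with the positive side predicting `significant`
and margins at ±1.  The boundary is defined by the zero level set; the ±1
level sets are the margins.  The fitted object carries the standard
modelling interface: `print`, `summary`, `coef`, `predict` (classes or
signed decision values) and `plot`.

```{r, eval = FALSE}
coh  <- simulate_cohort(cohort_config(n_subjects = 16, seed = 1))
meas <- cohort_measures(coh)
X    <- feature_matrix(meas, feature_set = reference_feature_set())
grp  <- assign_groups(setNames(coh$groups$cmj_change, coh$groups$subject_id))
fit  <- fatigue_classifier(X[grp$subject_id, ], grp$label)
summary(fit)
plot(fit)
```

## The synthetic cohort generator

No public per-subject recordings exist for this kind of protocol, so the
package ships a generator whose defaults *are* the study conditions it
emulates: 16 subjects (8 F / 8 M) with anthropometrics drawn from
sex-specific distributions (e.g. female height 169.1 ± 5.9 cm), resting
cardiovascular baselines HR 98.5 ± 10.9 bpm, SDNN 58 ± 19.7 ms, PAT
273.4 ± 21.6 ms, and cohort-mean fatigued/rested multipliers HR ×1.095,
SDNN ×0.788, RMSSD ×0.707, normalized PAT ×0.980.

**NN series** are built from a constant base interval plus a slow
oscillation (0.1 Hz, sliding down to 0.04 Hz when a low RMSSD/SDNN ratio
demands it), a fast respiratory oscillation (0.25 Hz) and white noise.
For a sinusoid of amplitude A and frequency f sampled at the beat period
T, the SDNN² contribution is A²/2 and the RMSSD² contribution is
4 sin²(πfT) times that; noise contributes 1× and 2×.  Solving this 2×3
system in closed form makes realized SDNN and RMSSD land within a few
percent of target; RMSSD targets above √2·SDNN (or below the
slow-oscillation floor) are rejected as infeasible rather than silently
missed.

**Waveforms** are template-based: Gaussian-bump P-QRS-T complexes with the
R-peak exactly at each beat time, and pulses of the form
`(x/τ)·exp(1 − x/τ)` whose linear leading edge starts exactly at the foot,
lagging the R-peak by the per-beat PAT (phase target + 3 ms white jitter).
True R and foot times are emitted as ground truth, so detectors are scored
against known answers instead of manual annotation.

**Fatigue structure.**  Each subject draws an *overall* state response per
measure — lognormal spread of 22% for SDNN, 18% for RMSSD and 10% for PAT
around
the cohort multipliers, reflecting the genuinely large day-to-day
variability of these measures — applied to resting and recovery phases
alike, plus a *rest-to-recovery ratio* effect whose fatigued-state mean is
group-dependent: significantly fatigued subjects suppress resting SDNN
relative to recovery by 18% more than mild ones, and their fatigued-state
recovery PAT dips to 0.84 of resting versus 0.95 for mild (SD 0.02, with
3× that spread on the rested day, where the balance carries no fatigue
information).  CMJ change is drawn at −0.6% (mild) vs −5.6% (significant),
SD 1.5, giving the whole-group mean near −3.1%.  The consequence — and the
design intent — is that raw between-state changes are noisy markers of the
fatigue group while the fatigued-state recovery-normalized composites
(SDNN and PAT families) carry the group signal, so stump screening
reliably surfaces one of each among its top features.

Blood pressure is constant within a state by default (a configurable
per-phase drift exists); raw PAT targets are derived from normalized
targets through the 1 ms/mmHg relation so the normalization stage is
exercised honestly.

**What the generator does not emulate**: ECG morphology pathology,
respiration–HRV coupling beyond a fixed 0.25 Hz band, motion artifacts,
ectopy, or BP measurement error.  Passing tests therefore demonstrate the
pipeline's correctness and its statistical behaviour under the modelled
structure — not detector robustness to pathological or artifact-laden
real-world signals.

## Numerical choices and problem sizes

* Detection tests run at 250–500 Hz on 1–5 min segments; full-session
  (29 min) detection is exercised once at 250 Hz on a 4-subject cohort.
  Statistical tests (screening stability) use 50 cohorts of n = 16 at the
  beat-annotation level, where waveform rendering is skipped because the
  generator's beat series are themselves ground truth.
* Minimum data rules: 30 NN intervals per HRV window and 10 matched beats
  per PAT window; thinner windows are flagged missing, never fabricated.
* All randomness is seed-derived; generators restore the caller's RNG
  state.  Identical config + seed gives byte-identical artifacts, and every
  pipeline output carries an FNV-1a hash of the resolved configuration.
* Degenerate cases are contracts, not surprises: constant features yield
  majority stumps (and 0.0 pooled LOOCV accuracy on balanced cohorts),
  zero-variance paired differences are an error rather than p = 0,
  constant columns yield undefined (missing) correlations.

## Known limitations

The classifier is an illustration of what the screened features support at
n = 16, not a validated clinical instrument; with 72 screened features and
16 subjects, selection effects are large and LOOCV metrics of the *chosen*
feature are optimistic.  The CMJ-based grouping threshold is a design
choice; alternative cuts change the labels.  Frequency-domain and
non-linear HRV are intentionally out of scope, as is automatic phase
detection from the HR trace — the schedule is data supplied by the
operator.
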