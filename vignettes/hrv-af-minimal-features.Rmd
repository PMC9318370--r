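---
title: "Minimal HRV feature sets for AF detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal HRV feature sets for AF detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Atrial fibrillation (AF) produces an irregular ventricular rhythm, while
sinus rhythm (SR) is comparatively regular.  Time-domain heart-rate
variability (HRV) descriptors computed from RR intervals — the durations of
consecutive cardiac cycles — therefore discriminate the two rhythms, and
they are cheap enough for wearable and implantable monitors.  The question
this package studies is *how few* descriptors suffice: features are ranked
by a minimum-redundancy maximum-relevance (MRMR) criterion on a training
split, classifiers are tuned by 5-fold cross-validation over nested prefix
feature sets of size 1–6, and performance is validated both in
cross-validation and "blindfold" — on patients entirely absent from
training, the only protocol that rules out per-patient data leakage.

The full study runs on annotated Holter databases.  This package
additionally ships a seeded synthetic cohort generator so that every stage
is exercisable, testable and reproducible at desk scale without downloads;
an optional text-annotation adapter (`read_rr_annotations()`) ingests
external QRS/rhythm annotation exports.

## The synthetic cohort model

Each virtual patient is one annotated RR stream.  Defaults
(`generator_config()`) are the package's study conditions and were chosen
once, on physiologic grounds, to reproduce the qualitative structure the
analysis assumes: successive-difference descriptors separate the classes
best, while marginal descriptors such as mean RR overlap substantially.

**Sinus rhythm.** Around a per-patient mean (lognormal, median 900 ms,
spread 160 ms), the series is a mean-reverting AR(1) fluctuation
(coefficient 0.8, innovation SD median 15 ms with per-patient lognormal
spread 0.5) plus two sinusoidal modulations with random phase: a
respiratory component (25 ms at 0.25 Hz) and a slow, Mayer-wave-like
component (40 ms at 0.05 Hz).  The slow component matters: without it, a
60 s window has almost no long-term dispersion and the Poincaré ratio
SD2/SD1 collapses below 1, which real SR segments do not show.  Finally,
premature supraventricular (ectopic) beats occur at a per-beat rate with
median 3% (per-patient lognormal spread 1.2, capped at 25%): the ectopic
interval is shortened to 75% of its value and the next interval absorbs the
difference as a compensatory pause.  Ectopy is the ingredient that makes
pRR50 the robust winner, exactly as on real recordings: each ectopic beat
adds two large successive differences, inflating the *mean-based*
difference statistics (RRdif, SDSuccRat, CV, SDRR) with heavy tails, while
the *bounded count* pRR50 moves by at most two pair-counts per event.

**Atrial fibrillation.** Independent gamma-distributed intervals around a
per-patient mean (lognormal, median 650 ms, spread 200 ms) with a
per-patient coefficient of variation drawn from a truncated normal
(centre 0.18, SD 0.08, truncated to [0.04, 0.35]) and a small per-patient
lag-1 blending (uniform on [0, 0.2], variance-preserving) so the Poincaré
cloud is not perfectly symmetric.  The low-CV tail produces AF patients
that genuinely resemble noisy SR — the hard cases that keep accuracy off
the ceiling.

**Plumbing.** A fraction (10%) of patients receive a single labeled
AF↔SR transition at 60% of the recording, exercising the rhythm-purity
filter; 1% of beats are replaced by out-of-range artifact durations
(uniformly 60–239 ms or 3001–6000 ms), exercising the duration filter.
Generated physiologic intervals are clamped to 240–3000 ms so that
injected artifacts are, by construction, the only out-of-range durations.
All randomness flows from one master seed through per-patient substreams
(`derive_seed()`), so cohorts are byte-identical across reruns and
independent of generation order.

**What the generator does not emulate.** Real Holter data contain
ventricular ectopy, atrial flutter and pacing, noise bursts correlated in
time, circadian drift in the mean, and artifact mechanisms far richer than
uniform out-of-range replacement.  Passing tests on synthetic cohorts
therefore demonstrate the correctness and the qualitative behavior of the
pipeline, not clinical performance; headline numbers on the real databases
are outside what the synthetic conditions can certify.

## Segmentation rules

Windows of 60 s tile each recording from its start (an interval belongs to
the window containing its opening beat; an `offset_s` config allows other
anchorings); only windows whose nominal span is fully covered are
considered.  A window survives iff (a) its rhythm labels are purely AF or
purely SR, (b) after removing intervals shorter than 240 ms or longer than
3000 ms the removed duration is *less than* 10% (6 s) of the nominal
60 s — removal at or above 6 s discards the window ("at least 10%" read
inclusively), and (c) at least 18 intervals remain.  The floor of 18 guards
degenerate feature inputs and sits just below the 20-interval minimum
implied by the 3000 ms cap; duration bookkeeping uses the nominal
60 000 ms, since the 10% rule is stated against total segment duration.
Beat-type labels are carried but only the duration rule removes intervals.
Retained intervals keep adjacency flags, and all successive-pair statistics
use only adjacent pairs: a pair bridging a removal gap is not a
physiological successive difference.

## The 13 descriptors

Distribution descriptors (meanRR, SDRR, RRrange, CV = SDRR/meanRR,
relRRrange = RRrange/meanRR) use all retained intervals; successive-pair
descriptors (pRR50, SD1, SD2, SD2/SD1, RRdif, relRRdif = RRdif/meanRR,
meanSuccRat, SDSuccRat) use valid adjacent pairs.  pRR50 counts pairs with
|ΔRR| ≥ 50 ms (inclusive).  SD1 and SD2 come from rotating the Poincaré
cloud onto the axes across and along the identity line —
SD((RR~n+1~ − RR~n~)/√2) and SD((RR~n+1~ + RR~n~)/√2) — which satisfies
SD1² + SD2² = Var(RR~n~) + Var(RR~n+1~) exactly.  All standard deviations
default to the sample convention (n − 1), the dominant choice in HRV
tooling; a `sd_type = "population"` switch exists for sensitivity checks.
A segment with SD1 = 0 has an undefined SD2/SD1 and is excluded with a
logged count rather than imputed: it cannot occur in non-degenerate
physiological 60 s data, and silent imputation would distort MRMR.

## Feature ranking

Per-feature AUC uses the Mann–Whitney rank-sum identity with midranks, AF
positive, reported as max(AUC, 1 − AUC) with the flip recorded.  MRMR is
greedy: the first pick maximizes relevance — the mutual information (MI)
between the feature and the class — and each later pick maximizes
relevance/redundancy (MIQ, the default, matching the documented criterion
of the toolbox implementation this harness mirrors), where redundancy is
the mean MI between the candidate and the already-selected features;
a difference form (MID) is available.  MI is the plug-in estimate on
equal-frequency bins (default 16; fewer cells when ties collapse quantile
breaks), log base 2, with the class treated as categorical.  The
redundancy denominator is floored at 10⁻¹² bits.  Ties break toward the
earlier feature in the pool.

One subtlety of the quotient form is worth recording: with exact MI
values, a feature that is pure noise has zero relevance and thus quotient
zero, so MIQ necessarily ranks a perfect duplicate of an informative
feature *above* noise (the duplicate's quotient MI/H is positive).  Under
MID the duplicate scores relevance − entropy, far below noise's ≈ 0, and
is ranked last.  Tests of the duplicate-versus-noise construction
therefore use MID; the pipeline default remains MIQ.

Feature selection runs on training-split rows only; the pipeline passes
nothing else.  Absolute MRMR scores depend on the discretization and are
not comparable across estimators — only orderings are used downstream.

## Classifier harness

Patients are split 2/3 : 1/3 per database tag (rounded, sampled without
replacement, seeded).  Seven families sit behind one fit/predict contract:
decision tree (`rpart`, Gini), K nearest neighbours (`class::knn`, odd K
so binary votes cannot tie), linear and RBF SVM (`e1071`), AdaBoost
(discrete AdaBoost.M1 over weighted depth-1 `rpart` stumps, implemented
in-package), random forest (`ranger`), and a single-hidden-layer neural
network (`nnet`; logistic hidden units — no installed single-layer fitter
offers ReLU, a deliberate substitution).  Features are z-scored for the
distance- and margin-based families (KNN, SVMs, ANN), with centre and
scale fit on training rows only — inside each fold during tuning; tree
ensembles are left unscaled.

Tuning is stratified 5-fold cross-validation over the training segments:
the grid point with the highest mean fold accuracy wins, ties to the
earlier point in grid order.  `default_grids()` spans the full search
ranges (tree depth 2–20, K = 1–51 odd, C over 10⁻²–10², γ over 10⁻³–10,
forest depth 4–16 × 50–200 trees, 25–200 boosting rounds, 4–64 hidden
units); `compact_grids()` covers the same ranges with 2–6 points per
family and is the pipeline default so that the full 7-family × 6-set ×
2-pool × 2-mode experiment finishes in about half a minute at the default
cohort size.  Folds are segment-level within the training split — the
blindfold arm is the leakage-safe contrast — and a patient-grouped split
is available via the same `split_by_patient()` machinery.

Blindfold evaluation refuses to run if any patient occurs on both sides
(a hard error, not a warning).  Metrics are accuracy, sensitivity,
specificity and PPV (AF positive, in percent) and the diagnostic odds
ratio DOR = (TP·TN)/(FP·FN); zero cells default to the Haldane
correction (+0.5 on every cell), with a strict policy that reports the
ratio as undefined.

## Problem sizes and reproducibility

The bundled analysis scripts and the acceptance script run the default
conditions: 20 patients per class, 10-minute recordings (≈ 370 usable
segments), all seven families, k = 1–6, both pools — about 35–40 s on one
CPU.  Ranking-stability checks use 40 patients per class over five seeds.
Every stage seed derives deterministically from one master seed, so a
repeated run reproduces every artifact exactly.

## Known limitations

With ~7 patients per class in the blindfold split, patient-level sampling
dominates the small-k blindfold metrics: a test split that happens to draw
low-dispersion AF patients can make a single-feature classifier transfer
poorly even when cross-validated accuracy is high — visible as
seed-to-seed swings in blindfold DOR at k ≤ 2.  This is the expected
behavior of patient-disjoint validation at desk scale, not an artifact of
the implementation; the real-data setting averages over two orders of
magnitude more segments.  The generator's realism limits are listed above;
frequency-domain and entropy HRV measures, QRS detection, and alternative
feature selectors are out of scope.
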