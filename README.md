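# hrvaf — minimal HRV feature sets for atrial fibrillation detection

`hrvaf` is an R package plus a staged analysis workflow for a question
that matters to anyone putting arrhythmia detection on a wearable: **how
few time-domain heart-rate-variability (HRV) descriptors are needed to
separate atrial fibrillation (AF) from sinus rhythm (SR) in 60 s
RR-interval segments?**  It is aimed at biomedical-signal researchers and
ML practitioners who want a fully reproducible, patient-leakage-aware
reference pipeline they can run at desk scale.

The pipeline:

1. **Cohort** — a seeded generator of annotated two-rhythm RR recordings
   (`generate_cohort()`): SR as a mean-reverting AR(1) series with
   respiratory and slow modulation plus occasional ectopic beats; AF as
   weakly correlated, high-dispersion gamma series; per-patient
   heterogeneity, labeled rhythm transitions and out-of-range artifacts.
   An adapter (`read_rr_annotations()`) ingests external text annotation
   exports instead.
2. **Segments** — non-overlapping pure-rhythm 60 s windows; RR intervals
   outside 240–3000 ms are removed, windows losing ≥ 6 s (10%) or mixing
   rhythms are discarded (`segment_cohort()`).
3. **Features** — 13 descriptors per segment (`build_feature_table()`):
   pRR50, SD1, SD2, SD2/SD1, SDRR, RRdif, CV, relRRdif, meanSuccRat,
   SDSuccRat, mean RR, RRrange, relRRrange.  pRR50 is the percentage of
   successive differences with |RR*ₙ₊₁* − RR*ₙ*| ≥ 50 ms; SD1/SD2 are the
   Poincaré-cloud dispersions across/along the identity line,
   SD1 = SD((RR*ₙ₊₁* − RR*ₙ*)/√2), SD2 = SD((RR*ₙ₊₁* + RR*ₙ*)/√2).
4. **Ranking** — per-feature ROC AUC (rank-sum identity) and greedy
   minimum-redundancy maximum-relevance selection
   (`mrmr_rank()`): first pick maximizes the feature–class mutual
   information I(f; y); later picks maximize I(f; y) / mean I(f; s) over
   the already selected s (quotient form; difference form available),
   with MI estimated by equal-frequency binning.  Ranking sees training
   rows only.
5. **Evaluation** — seven classifier families (DT, KNN, linear/RBF SVM,
   AdaBoost, random forest, single-layer ANN) over the 1–6-feature MRMR
   prefixes (`run_experiment_matrix()`): metaparameters tuned by
   stratified 5-fold cross-validation on the training split, then
   blindfold validation on held-out patients (any patient overlap is a
   hard error).  Reported per cell: confusion counts, accuracy,
   sensitivity, specificity, PPV and the diagnostic odds ratio
   DOR = (TP·TN)/(FP·FN) (Haldane-corrected on zero cells).

## Worked example

The staged scripts run the whole study and leave their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R 1     # cohort (master seed 1)
Rscript analysis/02_segment.R
Rscript analysis/03_features.R
Rscript analysis/04_rank.R 1
Rscript analysis/05_evaluate.R 1
Rscript analysis/06_report.R
```

Stage 3 prints the class structure of the cohort — AF segments have far
larger successive-difference variability, while mean RR overlaps:

```
feature table: 371 segments x 13 features
per-class medians of the headline descriptors:
  class    pRR50  SD2_SD1         CV   meanRR
1    AF 64.06015 1.148962 0.15034535 633.1284
2    SR 22.41379 0.901003 0.08262491 940.2198
```

Stage 4 ranks features on the training split; pRR50 leads the MRMR
ordering, followed by low-redundancy complements rather than the
next-best AUC features:

```
MRMR ranking, full pool:
   rank     feature  score
1     1       pRR50 0.6998
2     2     SD2_SD1 0.4158
3     3      meanRR 0.4505
4     4  relRRrange 0.3602
5     5    relRRdif 0.3338
6     6          CV 0.2846
...
```

Stage 5 tunes and validates all families; a typical summary line:

```
best blindfold accuracy: 100.0% (ANN, 5 features, DOR 17115)
```

and stage 6 writes the accuracy-versus-k table, the blindfold DOR
contrast with and without pRR50, and histogram/accuracy figures.

The same run is available in one call from R:

```r
library(hrvaf)
res <- run_pipeline(run_config(seed = 1))
render_report(res)$cv_accuracy
```

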