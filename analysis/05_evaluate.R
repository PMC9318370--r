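#!/usr/bin/env Rscript
# Stage 5: tune (5-fold CV on the training split) and blindfold-validate
# all seven classifier families over the 1..6-feature MRMR prefixes, with
# and without pRR50 in the pool.
#
# Usage: Rscript analysis/05_evaluate.R [seed]

suppressPackageStartupMessages(library(hrvaf))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

tab <- read_tsv("results/feature_table.tsv")
man <- cohort_manifest(read_cohort("results/cohort"))
split <- split_by_patient(man, 2 / 3, derive_seed(seed, "split"))
parts <- apply_split(tab, split)

rankings <- list(full = mrmr_rank(parts$train),
                 no_pRR50 = mrmr_rank(parts$train,
                                      setdiff(hrv_feature_names(), "pRR50")))
report <- run_experiment_matrix(parts$train, parts$test, rankings,
                                k_max = 6, seed = derive_seed(seed, "evaluate"))
write_tsv(report, "results/eval_report.tsv")

bf <- report[report$mode == "blindfold" & report$pool == "full", ]
best <- bf[which.max(bf$accuracy), ]
cat(sprintf("best blindfold accuracy: %.1f%% (%s, %d features, DOR %.0f)\n",
            best$accuracy, best$family, best$n_features, best$dor))
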