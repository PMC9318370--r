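#!/usr/bin/env Rscript
# Stage 4: split patients 2/3 : 1/3 per database and rank features on the
# training rows only -- per-feature AUC, MRMR over the full pool, and MRMR
# after excluding pRR50.
#
# Usage: Rscript analysis/04_rank.R [seed]

suppressPackageStartupMessages(library(hrvaf))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

tab <- read_tsv("results/feature_table.tsv")
man <- cohort_manifest(read_cohort("results/cohort"))
split <- split_by_patient(man, 2 / 3, derive_seed(seed, "split"))
write_tsv(rbind(cbind(split$train_patients, set = "training"),
                cbind(split$test_patients, set = "test")),
          "results/split.tsv")
parts <- apply_split(tab, split)

auc <- auc_rank(parts$train)
full <- mrmr_rank(parts$train)
reduced <- mrmr_rank(parts$train, setdiff(hrv_feature_names(), "pRR50"))
write_ranking(auc, "results/ranking_auc.yaml")
write_ranking(full, "results/ranking_full.yaml")
write_ranking(reduced, "results/ranking_no_pRR50.yaml")

cat("AUC ranking (training split):\n"); print(auc)
cat("\nMRMR ranking, full pool:\n"); print(full)
cat("\nMRMR ranking without pRR50:\n"); print(reduced)
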