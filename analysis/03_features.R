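#!/usr/bin/env Rscript
# Stage 3: compute the 13 HRV descriptors per segment (gap-aware: pairs
# spanning a removed interval are excluded from difference statistics).
#
# Usage: Rscript analysis/03_features.R

suppressPackageStartupMessages(library(hrvaf))

segments <- read_segments("results/segments.tsv")
tab <- build_feature_table(segments)
write_tsv(tab, "results/feature_table.tsv")

cat(sprintf("feature table: %d segments x %d features\n",
            nrow(tab), length(hrv_feature_names())))
cat("per-class medians of the headline descriptors:\n")
print(aggregate(tab[, c("pRR50", "SD2_SD1", "CV", "meanRR")],
                by = list(class = tab$rhythm_class), median))
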