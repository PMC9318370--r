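#!/usr/bin/env Rscript
# Stage 2: cut recordings into pure 60 s segments and apply the artifact
# filters (remove RR outside 240-3000 ms; discard windows losing >= 6 s or
# mixing rhythms).
#
# Usage: Rscript analysis/02_segment.R

suppressPackageStartupMessages(library(hrvaf))

cohort <- read_cohort("results/cohort")
out <- segment_cohort(cohort, segmentation_config())
write_segments(out$segments, "results/segments.tsv")
write_tsv(out$qc, "results/segment_qc.tsv")
write_tsv(summarize_filtering(out$qc), "results/filtering_summary.tsv")

cat(sprintf("%d windows considered, %d segments kept\n",
            nrow(out$qc), length(out$segments)))
print(table(out$qc$outcome))
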