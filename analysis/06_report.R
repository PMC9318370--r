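#!/usr/bin/env Rscript
# Stage 6: summary tables and figures from the completed run.
#
# Usage: Rscript analysis/06_report.R

suppressPackageStartupMessages(library(hrvaf))

report <- read_tsv("results/eval_report.tsv")
tab <- read_tsv("results/feature_table.tsv")

# mean (SD) cross-validated accuracy per family and feature-set size
cv <- report[report$mode == "cv5" & report$pool == "full", ]
acc <- reshape(cv[, c("family", "n_features", "cv_acc_mean")],
               direction = "wide", idvar = "family", timevar = "n_features")
names(acc) <- sub("cv_acc_mean.", "k", names(acc))
write_tsv(acc, "results/cv_accuracy_by_k.tsv")
cat("5-fold CV accuracy (%) by number of features:\n")
print(acc, digits = 4, row.names = FALSE)

# blindfold DOR contrast with and without pRR50
bf <- report[report$mode == "blindfold", ]
dor <- aggregate(dor ~ pool + n_features, bf, median)
write_tsv(dor, "results/blindfold_dor_by_pool.tsv")
cat("\nmedian blindfold DOR per pool:\n")
print(reshape(dor, direction = "wide", idvar = "pool",
              timevar = "n_features"), row.names = FALSE)

# figures: feature histograms by class and accuracy-versus-k curves
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
grDevices::png("results/figures/feature_histograms.png", 900, 600)
op <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
for (f in c("pRR50", "SD2_SD1", "CV", "meanRR", "relRRdif", "relRRrange")) {
  af <- tab[[f]][tab$rhythm_class == "AF"]
  sr <- tab[[f]][tab$rhythm_class == "SR"]
  br <- seq(min(tab[[f]]), max(tab[[f]]), length.out = 30)
  hist(sr, breaks = br, col = rgb(0, 0, 1, 0.5), main = f, xlab = f)
  hist(af, breaks = br, col = rgb(1, 0.5, 0, 0.5), add = TRUE)
}
par(op); dev.off()

grDevices::png("results/figures/accuracy_by_k.png", 900, 600)
op <- par(mfrow = c(2, 4), mar = c(4, 4, 2, 1))
for (fam in unique(report$family)) {
  d <- report[report$family == fam & report$pool == "full", ]
  cvd <- d[d$mode == "cv5", ]; bfd <- d[d$mode == "blindfold", ]
  plot(cvd$n_features, cvd$accuracy, type = "b", col = "blue", pch = 16,
       ylim = range(d$accuracy), xlab = "features", ylab = "accuracy (%)",
       main = fam)
  lines(bfd$n_features, bfd$accuracy, type = "b", col = "darkorange", pch = 17)
}
par(op); dev.off()
cat("\nfigures written under results/figures/\n")
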