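#!/usr/bin/env Rscript
# Step 3 — clinical filtering and differential statistics.
#
# Applies the low-severity exclusion (retain patients with MADRS >= 20 or
# IDS-C30 >= 24; controls always kept), then compares editing features
# between groups (Ctrl vs merged MDD, Ctrl vs DEP, Ctrl vs SA, DEP vs SA)
# with the Wilcoxon rank-sum test and Welch's t-test, BH-adjusted within
# each comparison. Also reports the inter-site correlation structure and
# the percent mean variation of each isoform in SA relative to controls.
#
# Inputs: results/subject_features.tsv (step 2).
# Outputs: results/differential.tsv, results/site_correlations.tsv,
# results/mean_variation.tsv.

library(editisland)

feats <- read.delim("results/subject_features.tsv")

analysis_set <- filter_analysis_set(feats)
excl <- attr(analysis_set, "excluded")
cat(sprintf("Analysis set after severity filter: %s (excluded: %s)\n",
            paste(sprintf("%s=%d", names(table(analysis_set$group)),
                          as.integer(table(analysis_set$group))),
                  collapse = ", "),
            paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")))

dt <- differential_table(analysis_set)
write.table(dt, "results/differential.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (cmp in unique(dt$comparison)) {
  sub <- dt[dt$comparison == cmp, ]
  cat(sprintf("%-12s: significant (BH<0.05): %s\n", cmp,
              paste(sub$feature[sub$sig], collapse = ", ")))
}

corr <- site_correlation_matrix(
  analysis_set[analysis_set$group == "Ctrl", ],
  grep("^site_", names(analysis_set), value = TRUE))
write.table(round(corr$r, 3), "results/site_correlations.tsv",
            sep = "\t", quote = FALSE)
cat(sprintf("Control inter-site correlations all positive: %s\n",
            all(corr$r[upper.tri(corr$r)] > 0)))

iso_cols <- grep("^iso_", names(analysis_set), value = TRUE)
ctrl_means <- colMeans(analysis_set[analysis_set$group == "Ctrl", iso_cols])
sa_means <- colMeans(analysis_set[analysis_set$group == "SA", iso_cols])
mv <- data.frame(isoform = sub("^iso_", "", iso_cols),
                 ctrl_mean = round(ctrl_means, 4),
                 sa_mean = round(sa_means, 4),
                 mean_variation_pct = round(
                   mean_variation(ctrl_means, sa_means), 2))
write.table(mv, "results/mean_variation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Percent mean variation, SA vs Ctrl:\n")
print(mv, row.names = FALSE)
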