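#!/usr/bin/env Rscript
# Step 4 — random-forest discrimination of suicide attempters vs controls.
#
# Stratified 2/3-1/3 split of the filtered SA and Ctrl subjects; features
# significant in the SA-vs-Ctrl differential table computed on the
# training split only; randomForest with mtry = 2 and ntree = 1000;
# held-out ROC with trapezoid AUC, stratified-bootstrap 95% CI (2000
# resamples), Youden operating point, and sensitivity at 90% specificity.
#
# Inputs: results/subject_features.tsv (step 2).
# Outputs: results/roc.tsv, results/classifier_report.json.

library(editisland)

feats <- read.delim("results/subject_features.tsv")
analysis_set <- filter_analysis_set(feats)

cfg <- classifier_config(seed = 1L)
res <- classify_sa_vs_ctrl(analysis_set, cfg)

write.table(res$report$roc, "results/roc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(
  auc = res$report$auc,
  auc_ci = as.list(res$report$auc_ci),
  sensitivity_youden = res$report$sensitivity,
  specificity_youden = res$report$specificity,
  sensitivity_at_90_specificity =
    res$report$at_fixed_specificity$sensitivity,
  selected_features = res$selected_features,
  n_train = length(res$split$train),
  n_test = as.list(res$report$n_test)
), "results/classifier_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("Train n = %d, test n = %d\n",
            length(res$split$train), length(res$split$test)))
cat(sprintf("Selected features: %s\n",
            paste(res$selected_features, collapse = ", ")))
print(res$report)
cat(sprintf("Sensitivity at 90%% specificity: %.1f%%\n",
            100 * res$report$at_fixed_specificity$sensitivity))

imp <- res$report$importance
if (!is.null(imp)) {
  top <- sort(imp[, "MeanDecreaseGini"], decreasing = TRUE)
  cat("Top features by Gini importance:",
      paste(utils::head(names(top), 3), collapse = ", "), "\n")
}
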