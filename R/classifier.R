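# Random-forest discriminator of suicide attempters versus controls.
# Features significant in the SA-vs-Ctrl differential table (computed on
# the training split only, to avoid leakage) are combined in a
# randomForest model (mtry = 2, ntree = 1000 by default); performance is
# reported on the held-out third as a ROC curve, AUC with stratified
# bootstrap CI, and sensitivity/specificity at the Youden-optimal point.

#' Classifier configuration
#'
#' @param trees Number of trees (default 1000).
#' @param mtry Candidate features per split (default 2).
#' @param folds Cross-validation folds for optional hyperparameter search
#'   (default 10).
#' @param train_fraction Fraction of subjects used for training (default
#'   2/3; stratified by class).
#' @param stratified Preserve class proportions in the split (default
#'   TRUE).
#' @param positive Positive class label (default `"SA"`).
#' @param boot_n Bootstrap resamples for the AUC CI (default 2000).
#' @param seed Random seed.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(trees = 1000, mtry = 2, folds = 10,
                              train_fraction = 2 / 3, stratified = TRUE,
                              positive = "SA", boot_n = 2000, seed = 1L) {
  stopifnot(trees >= 1, mtry >= 1, folds >= 2,
            train_fraction > 0, train_fraction < 1)
  structure(list(trees = as.integer(trees), mtry = as.integer(mtry),
                 folds = as.integer(folds),
                 train_fraction = train_fraction,
                 stratified = isTRUE(stratified),
                 positive = positive, boot_n = as.integer(boot_n),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# round half up
round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Per-class training counts are `round(fraction * class size)` (half up),
#' then the largest class is adjusted so the overall training size equals
#' `round(fraction * n)`. Deterministic given the seed; train and test are
#' disjoint and exhaustive.
#'
#' @param labels Class label vector.
#' @param cfg A `classifier_config`.
#' @return List: `train`, `test` (integer index vectors).
#' @export
split_train_test <- function(labels, cfg = classifier_config()) {
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every class needs >= 2 subjects to split (got: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
  }
  set.seed(cfg$seed)
  n <- length(labels)
  target_total <- round_half_up(cfg$train_fraction * n)
  if (cfg$stratified) {
    n_train <- round_half_up(cfg$train_fraction * as.numeric(tab))
    names(n_train) <- names(tab)
    diff <- target_total - sum(n_train)
    if (diff != 0) {
      big <- names(tab)[which.max(tab)]
      n_train[big] <- n_train[big] + diff
    }
    train <- unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      sample(idx, n_train[cl])
    }), use.names = FALSE)
  } else {
    train <- sample(n, target_total)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Select features significant in a differential table
#'
#' Keeps features with BH-adjusted p below 0.05 in the given comparison
#' (adjusted Wilcoxon p). Falls back to all features, with a warning, when
#' nothing is significant.
#'
#' @param diff_tab Output of [differential_table()].
#' @param comparison Which comparison row-set to use (default
#'   `"Ctrl vs SA"`).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of feature names.
#' @export
select_features <- function(diff_tab, comparison = "Ctrl vs SA",
                            alpha = 0.05) {
  tab <- diff_tab[diff_tab$comparison == comparison, , drop = FALSE]
  if (nrow(tab) == 0) stop("comparison not present in differential table")
  sel <- tab$feature[tab$p_w_adj < alpha]
  if (length(sel) == 0) {
    warning("no significant features; falling back to all features")
    sel <- tab$feature
  }
  sel
}

#' Train the random forest
#'
#' Bagged classification trees via the randomForest package. When
#' `tune = TRUE`, mtry is chosen by k-fold cross-validated accuracy over a
#' small grid before the final fit.
#'
#' @param x data.frame/matrix of features (training rows only).
#' @param y Class labels (factor or coercible).
#' @param cfg A `classifier_config`.
#' @param tune Cross-validate mtry over `1..min(p, 4)` (default FALSE;
#'   the shipped default mtry = 2 is used as-is).
#' @return A `randomForest` fit (attribute `mtry_cv` holds the CV table
#'   when tuned).
#' @export
train_random_forest <- function(x, y, cfg = classifier_config(),
                                tune = FALSE) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training data contain a single class")
  x <- as.data.frame(x)
  mtry <- min(cfg$mtry, ncol(x))
  cv_tab <- NULL
  if (tune) {
    set.seed(cfg$seed)
    grid <- unique(pmin(seq_len(min(ncol(x), 4)), ncol(x)))
    folds <- sample(rep_len(seq_len(cfg$folds), length(y)))
    acc <- vapply(grid, function(m) {
      hits <- 0L
      for (f in seq_len(cfg$folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2) next
        fit <- randomForest::randomForest(
          x[tr, , drop = FALSE], y[tr],
          ntree = max(100L, cfg$trees %/% 4L), mtry = m)
        hits <- hits + sum(stats::predict(fit, x[!tr, , drop = FALSE]) ==
                             y[!tr])
      }
      hits / length(y)
    }, numeric(1))
    cv_tab <- data.frame(mtry = grid, cv_accuracy = acc)
    mtry <- grid[which.max(acc)]
  }
  set.seed(cfg$seed)
  fit <- randomForest::randomForest(x, y, ntree = cfg$trees, mtry = mtry,
                                    importance = TRUE)
  attr(fit, "mtry_cv") <- cv_tab
  fit
}

#' Evaluate a classifier on a held-out test set
#'
#' Builds the ROC from the model's positive-class probabilities, computes
#' the trapezoid AUC with a stratified-bootstrap 95% CI, and reports
#' sensitivity/specificity at the maximum-Youden operating point (or at a
#' fixed specificity when requested).
#'
#' @param model A fit from [train_random_forest()] (or any object whose
#'   `predict(..., type = "prob")` yields class probabilities), or a
#'   numeric score vector already aligned with `y_test`.
#' @param x_test,y_test Held-out features and labels.
#' @param cfg A `classifier_config`.
#' @param fixed_specificity Optional specificity at which to also report
#'   sensitivity (e.g. 0.9).
#' @return List of class `classifier_report`: `roc` (data.frame FPR, TPR,
#'   threshold), `auc`, `auc_ci`, `sensitivity`, `specificity`,
#'   `threshold`, optional `at_fixed_specificity`, `importance`,
#'   `n_test` (per class).
#' @export
evaluate_classifier <- function(model, x_test, y_test,
                                cfg = classifier_config(),
                                fixed_specificity = NULL) {
  y_test <- as.factor(y_test)
  if (length(unique(y_test)) < 2) {
    stop("test set contains a single class; AUC undefined")
  }
  if (is.numeric(model)) {
    scores <- model
    imp <- NULL
  } else {
    pr <- stats::predict(model, as.data.frame(x_test), type = "prob")
    scores <- pr[, cfg$positive]
    imp <- if (inherits(model, "randomForest")) {
      randomForest::importance(model)
    } else NULL
  }
  resp <- factor(ifelse(y_test == cfg$positive, "pos", "neg"),
                 levels = c("neg", "pos"))
  roc_obj <- pROC::roc(response = resp, predictor = scores,
                       levels = c("neg", "pos"), direction = "<",
                       quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc_obj))
  set.seed(cfg$seed)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(
    roc_obj, method = "bootstrap", boot.n = cfg$boot_n,
    boot.stratified = TRUE, progress = "none")))
  co <- pROC::coords(roc_obj, x = "all", ret = c("threshold", "specificity",
                                                 "sensitivity"))
  youden <- pROC::coords(roc_obj, x = "best", best.method = "youden",
                         ret = c("threshold", "specificity", "sensitivity"))
  if (nrow(youden) > 1) youden <- youden[1, , drop = FALSE]
  report <- list(
    roc = data.frame(FPR = 1 - co$specificity, TPR = co$sensitivity,
                     threshold = co$threshold),
    auc = auc,
    auc_ci = c(lower = ci[1], upper = ci[3]),
    sensitivity = youden$sensitivity,
    specificity = youden$specificity,
    threshold = youden$threshold,
    importance = imp,
    n_test = table(y_test)
  )
  if (!is.null(fixed_specificity)) {
    fx <- pROC::coords(roc_obj, x = fixed_specificity,
                       input = "specificity",
                       ret = c("specificity", "sensitivity"))
    report$at_fixed_specificity <- fx
  }
  class(report) <- "classifier_report"
  report
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("AUC = %.3f [%.3f; %.3f]\n", x$auc,
              x$auc_ci["lower"], x$auc_ci["upper"]))
  cat(sprintf("Youden operating point: sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  cat("Test set:", paste(sprintf("%s=%d", names(x$n_test),
                                 as.integer(x$n_test)), collapse = ", "), "\n")
  invisible(x)
}

#' End-to-end discrimination of SA versus Ctrl
#'
#' Splits the cohort (stratified 2/3 train), selects significant features
#' on the training set only, trains the random forest, and evaluates on
#' the held-out third.
#'
#' @param features Feature data.frame from [cohort_features()] (needs
#'   `group` plus feature columns).
#' @param cfg A `classifier_config`.
#' @param groups The two classes to discriminate (default Ctrl vs SA).
#' @param tune Passed to [train_random_forest()].
#' @return List: `report` (`classifier_report`), `model`,
#'   `selected_features`, `split`.
#' @export
classify_sa_vs_ctrl <- function(features, cfg = classifier_config(),
                                groups = c("Ctrl", "SA"), tune = FALSE) {
  dat <- features[features$group %in% groups, , drop = FALSE]
  feature_cols <- setdiff(
    names(dat)[vapply(dat, is.numeric, logical(1))],
    c("MADRS", "IDSC30"))
  labels <- factor(dat$group, levels = groups)
  split <- split_train_test(labels, cfg)

  cmp <- paste(groups, collapse = " vs ")
  train_dat <- dat[split$train, , drop = FALSE]
  diff_tab <- differential_table(train_dat, feature_cols,
                                 comparisons = cmp)
  sel <- select_features(diff_tab, comparison = cmp)

  model <- train_random_forest(train_dat[, sel, drop = FALSE],
                               labels[split$train], cfg, tune = tune)
  report <- evaluate_classifier(model, dat[split$test, sel, drop = FALSE],
                                labels[split$test], cfg,
                                fixed_specificity = 0.9)
  list(report = report, model = model, selected_features = sel,
       split = split, differential = diff_tab)
}
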