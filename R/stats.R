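# Clinical filtering and group-comparison statistics. Editing features are
# compared between groups with the Wilcoxon rank-sum test and Welch's
# t-test; p-values are Benjamini-Hochberg adjusted across the feature
# family within each pairwise comparison; descriptives are mean +/- SEM.

#' Classify depression severity from MADRS / IDS-C30
#'
#' Bins: low 7 <= MADRS <= 19, moderate 20 <= MADRS <= 34, severe
#' MADRS >= 35 (IDS-C30 bins 12-23 / 24-36 / >= 37 used only when MADRS is
#' missing; MADRS takes precedence when both are present). Controls always
#' map to `none`.
#'
#' @param group Character vector of group labels (`Ctrl`, `DEP`, `SA`).
#' @param madrs,idsc30 Integer score vectors (NA = missing).
#' @return Factor with levels none < low < moderate < severe.
#' @export
classify_severity <- function(group, madrs, idsc30) {
  n <- length(group)
  stopifnot(length(madrs) == n, length(idsc30) == n)
  bin_madrs <- function(m) {
    if (m >= 35) "severe" else if (m >= 20) "moderate"
    else if (m >= 7) "low" else "none"
  }
  bin_idsc <- function(i) {
    if (i >= 37) "severe" else if (i >= 24) "moderate"
    else if (i >= 12) "low" else "none"
  }
  out <- character(n)
  for (k in seq_len(n)) {
    if (group[k] == "Ctrl") {
      out[k] <- "none"
    } else if (!is.na(madrs[k])) {
      out[k] <- bin_madrs(madrs[k])
    } else if (!is.na(idsc30[k])) {
      out[k] <- bin_idsc(idsc30[k])
    } else {
      stop("patient with both severity scores missing")
    }
  }
  factor(out, levels = c("none", "low", "moderate", "severe"),
         ordered = TRUE)
}

#' Drop low-severity patients from the analysis set
#'
#' Controls are always retained; patients are retained when
#' `MADRS >= 20` or `IDSC30 >= 24` (the boundary that separates the
#' low-severity bin from moderate-and-above on either scale). The numbers
#' excluded per group are attached as attribute `excluded`.
#'
#' @param records data.frame with `group`, `MADRS`, `IDSC30`.
#' @return Filtered data.frame (attribute `excluded`: named counts).
#' @export
filter_analysis_set <- function(records) {
  keep <- records$group == "Ctrl" |
    (!is.na(records$MADRS) & records$MADRS >= 20) |
    (!is.na(records$IDSC30) & records$IDSC30 >= 24)
  out <- records[keep, , drop = FALSE]
  excl <- table(factor(records$group[!keep],
                       levels = unique(records$group)))
  attr(out, "excluded") <- c(excl)
  out
}

#' Table-style severity breakdown to subject records
#'
#' Expands per-bin counts (low / moderate / high / very high) into minimal
#' records with a representative MADRS score per bin, for checking the
#' retention arithmetic of the low-severity exclusion.
#'
#' @param counts Named integer vector with names `low`, `moderate`,
#'   `high`, `very_high`.
#' @param group Group label for the expanded records.
#' @return data.frame with `group`, `MADRS`, `IDSC30`.
#' @export
records_from_severity_counts <- function(counts, group) {
  rep_madrs <- c(low = 15L, moderate = 27L, high = 35L, very_high = 45L)
  stopifnot(all(names(counts) %in% names(rep_madrs)))
  data.frame(
    group = group,
    MADRS = rep(rep_madrs[names(counts)], times = counts),
    IDSC30 = NA_integer_,
    row.names = NULL
  )
}

#' Printed severity breakdown of the patient groups
#'
#' @return List with integer vectors `DEP` and `SA` (counts per severity
#'   bin among the recruited patients).
#' @export
cohort_severity_breakdown <- function() {
  list(
    DEP = c(low = 19L, moderate = 41L, high = 31L, very_high = 10L),
    SA  = c(low = 8L, moderate = 36L, high = 30L, very_high = 10L)
  )
}

#' Wilcoxon rank-sum test
#'
#' Two-sided; exact enumeration for small untied samples, normal
#' approximation with tie correction otherwise (the behaviour of
#' [stats::wilcox.test()]). Constant pooled data yields p = 1 with a
#' warning rather than an error.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @return List: `statistic` (W), `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(c(x, y)) == 0) {
    warning("constant pooled data; p set to 1")
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Welch's t-test from summary statistics
#'
#' @param mean_x,sd_x,n_x First group's mean, SD, size.
#' @param mean_y,sd_y,n_y Second group's mean, SD, size.
#' @return List: `t`, `df` (Satterthwaite), `p.value` (two-sided).
#' @export
welch_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  stopifnot(n_x >= 2, n_y >= 2, sd_x > 0 || sd_y > 0)
  vx <- sd_x^2 / n_x
  vy <- sd_y^2 / n_y
  t <- (mean_x - mean_y) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  list(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Welch's t-test on raw data
#'
#' @param x,y Numeric samples.
#' @return List: `t`, `df`, `p.value`.
#' @export
welch_t <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (order-preserving, capped at 1).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pairwise Pearson correlations among editing features
#'
#' @param features data.frame (or matrix) of numeric feature columns.
#' @param cols Columns to correlate (default: all numeric columns).
#' @return List: `r` (correlations; NA for zero-variance features) and
#'   `p` (two-sided test p-values; diagonal NA).
#' @export
site_correlation_matrix <- function(features, cols = NULL) {
  m <- as.data.frame(features)
  if (is.null(cols)) {
    cols <- names(m)[vapply(m, is.numeric, logical(1))]
  }
  m <- as.matrix(m[, cols, drop = FALSE])
  stopifnot(nrow(m) >= 3)
  k <- ncol(m)
  r <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  p <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  sds <- apply(m, 2, stats::sd)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (sds[i] == 0 || sds[j] == 0) next
      if (i == j) { r[i, j] <- 1; next }
      ct <- stats::cor.test(m[, i], m[, j])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Percent mean variation of a case group versus controls
#'
#' `100 * (case - control) / control`; undefined (NA) when the control
#' mean is zero.
#'
#' @param control_mean,case_mean Group means (vectorised).
#' @return Percent variation.
#' @export
mean_variation <- function(control_mean, case_mean) {
  ifelse(control_mean == 0, NA_real_,
         100 * (case_mean - control_mean) / control_mean)
}

#' Housekeeping-normalised qPCR expression
#'
#' Second-derivative absolute quantities of a target gene divided by the
#' geometric mean of the four housekeeping genes.
#'
#' @param quantities Named numeric vector of per-gene quantities (> 0).
#' @param target Target gene name.
#' @param housekeeping Housekeeping gene names (default HPRT1, GAPDH, TBP,
#'   PGK1).
#' @return Normalised expression (scalar).
#' @export
qpcr_relative_expression <- function(quantities, target,
                                     housekeeping = c("HPRT1", "GAPDH",
                                                      "TBP", "PGK1")) {
  stopifnot(target %in% names(quantities),
            all(housekeeping %in% names(quantities)))
  hk <- quantities[housekeeping]
  if (any(hk <= 0)) stop("housekeeping quantities must be > 0")
  unname(quantities[target] / exp(mean(log(hk))))
}

#' Differential table across group comparisons
#'
#' For each requested comparison and each feature: group means +/- SEM,
#' Wilcoxon rank-sum and Welch t statistics with two-sided p-values, and
#' BH-adjusted p-values (adjusted per test across the feature family
#' within that comparison). `MDD` denotes the merged DEP + SA group. The
#' significance flag uses the adjusted Wilcoxon p at 0.05; the adjusted
#' Welch p is reported alongside.
#'
#' @param features data.frame with `group` and numeric feature columns.
#' @param feature_cols Feature column names (default: all numeric columns
#'   except MADRS/IDSC30).
#' @param comparisons Character vector among `"Ctrl vs MDD"`,
#'   `"Ctrl vs DEP"`, `"Ctrl vs SA"`, `"DEP vs SA"`.
#' @return data.frame: feature, comparison, mean/SEM per side, W, p_w,
#'   t, df, p_t, p_w_adj, p_t_adj, sig.
#' @export
differential_table <- function(features, feature_cols = NULL,
                               comparisons = c("Ctrl vs MDD", "Ctrl vs DEP",
                                               "Ctrl vs SA", "DEP vs SA")) {
  valid <- c("Ctrl vs MDD", "Ctrl vs DEP", "Ctrl vs SA", "DEP vs SA")
  stopifnot(all(comparisons %in% valid))
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(
      names(features)[vapply(features, is.numeric, logical(1))],
      c("MADRS", "IDSC30"))
  }
  grp <- features$group
  side_idx <- function(side) {
    if (side == "MDD") grp %in% c("DEP", "SA") else grp == side
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))

  out <- list()
  for (cmp in comparisons) {
    sides <- strsplit(cmp, " vs ", fixed = TRUE)[[1]]
    ia <- side_idx(sides[1]); ib <- side_idx(sides[2])
    if (sum(ia) < 2 || sum(ib) < 2) {
      stop("comparison '", cmp, "' has a missing or too-small group")
    }
    rows <- lapply(feature_cols, function(fc) {
      x <- features[[fc]][ia]; y <- features[[fc]][ib]
      w <- wilcoxon_rank_sum(x, y)
      tt <- welch_t(x, y)
      data.frame(feature = fc, comparison = cmp,
                 mean_a = mean(x), sem_a = sem(x),
                 mean_b = mean(y), sem_b = sem(y),
                 W = w$statistic, p_w = w$p.value,
                 t = tt$t, df = tt$df, p_t = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_w_adj <- bh_adjust(tab$p_w)
    tab$p_t_adj <- bh_adjust(tab$p_t)
    tab$sig <- tab$p_w_adj < 0.05
    out[[cmp]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
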