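# End-to-end driver: simulate -> quantify -> test -> classify, from one
# nested config, writing per-stage TSV/JSON outputs and a reproducibility
# manifest (config snapshot, seeds, package version, output checksums).

default_pipeline_config <- function() {
  list(
    simulate = list(seed = 1L, write_fastq = FALSE),
    quantify = list(detection_threshold = 0.1, isoform_threshold = 0.1),
    test = list(comparisons = c("Ctrl vs MDD", "Ctrl vs DEP",
                                "Ctrl vs SA", "DEP vs SA"),
                severity_filter = TRUE),
    classify = list(seed = 1L, trees = 1000L, mtry = 2L)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Stages run in order: simulate (cohort with replicate structure),
#' quantify (site calls, isoform profiles, subject feature table), test
#' (severity filter + differential statistics + correlations), classify
#' (random forest SA vs Ctrl). Any stage failure aborts with the stage
#' name; outputs of completed stages are preserved. A `manifest.json`
#' records the config, seeds, package version and MD5 checksums of every
#' output file.
#'
#' @param config Nested list (sections `simulate`, `quantify`, `test`,
#'   `classify`) or path to a YAML file with those sections. Unknown
#'   sections are an error; missing keys fall back to defaults.
#'   `simulate` accepts the arguments of [cohort_config()] plus
#'   `write_fastq`.
#' @param out_dir Output directory (created).
#' @return List with the in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  known <- c("simulate", "quantify", "test", "classify")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  }
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  ## simulate
  sim_cfg_args <- cfg$simulate
  write_fastq <- isTRUE(sim_cfg_args$write_fastq)
  sim_cfg_args$write_fastq <- NULL
  cohort <- stage("simulate", {
    ccfg <- do.call(cohort_config, sim_cfg_args)
    simulate_cohort(ccfg,
                    out_dir = if (write_fastq) file.path(out_dir, "fastq"))
  })

  ## quantify
  qcfg <- site_calling_config(
    detection_threshold = cfg$quantify$detection_threshold,
    isoform_threshold = cfg$quantify$isoform_threshold)
  quant <- stage("quantify", cohort_features(cohort, qcfg))
  f_sites <- file.path(out_dir, "site_calls.tsv")
  utils::write.table(quant$site_calls, f_sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_feat <- file.path(out_dir, "subject_features.tsv")
  utils::write.table(quant$features, f_feat, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, f_sites, f_feat)

  ## test
  test_res <- stage("test", {
    feats <- quant$features
    if (isTRUE(cfg$test$severity_filter)) {
      feats <- filter_analysis_set(feats)
    }
    dt <- differential_table(feats, comparisons = cfg$test$comparisons)
    feat_cols <- grep("^(site|iso)_", names(feats), value = TRUE)
    corr <- site_correlation_matrix(feats, grep("^site_", names(feats),
                                                value = TRUE))
    list(features = feats, differential = dt, correlation = corr)
  })
  f_diff <- file.path(out_dir, "differential.tsv")
  utils::write.table(test_res$differential, f_diff, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  f_corr <- file.path(out_dir, "site_correlations.tsv")
  utils::write.table(as.data.frame(test_res$correlation$r), f_corr,
                     sep = "\t", quote = FALSE, row.names = TRUE)
  outputs <- c(outputs, f_diff, f_corr)

  ## classify
  clf <- stage("classify", {
    ccfg <- classifier_config(trees = cfg$classify$trees,
                              mtry = cfg$classify$mtry,
                              seed = cfg$classify$seed)
    classify_sa_vs_ctrl(test_res$features, ccfg)
  })
  f_roc <- file.path(out_dir, "roc.tsv")
  utils::write.table(clf$report$roc, f_roc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_rep <- file.path(out_dir, "classifier_report.json")
  jsonlite::write_json(list(
    auc = clf$report$auc,
    auc_ci = as.list(clf$report$auc_ci),
    sensitivity = clf$report$sensitivity,
    specificity = clf$report$specificity,
    selected_features = clf$selected_features,
    n_test = as.list(clf$report$n_test)
  ), f_rep, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, f_roc, f_rep)

  ## manifest
  manifest <- list(
    package = "editisland",
    version = as.character(utils::packageVersion("editisland")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    seeds = list(simulate = cfg$simulate$seed, classify = cfg$classify$seed),
    checksums = as.list(tools::md5sum(outputs))
  )
  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  list(cohort = cohort, quant = quant, test = test_res, classifier = clf,
       manifest = manifest, out_dir = out_dir)
}

#' Summarise a completed pipeline run
#'
#' Produces a short text summary from the files in a result directory:
#' called sites, top isoforms, significant features per comparison, and
#' classifier performance. Missing stages are listed instead of failing.
#'
#' @param dir Result directory from [run_pipeline()].
#' @return Character vector of summary lines (also printed).
#' @export
pipeline_report <- function(dir) {
  lines <- character(0)
  missing <- character(0)

  f <- file.path(dir, "site_calls.tsv")
  if (file.exists(f)) {
    sc <- utils::read.delim(f)
    lines <- c(lines, sprintf("Called sites (> threshold): %d of %d [%s]",
                              sum(sc$pass), nrow(sc),
                              paste(sc$label[sc$pass], collapse = ", ")))
  } else missing <- c(missing, "quantify")

  f <- file.path(dir, "subject_features.tsv")
  if (file.exists(f)) {
    feats <- utils::read.delim(f)
    iso_cols <- grep("^iso_", names(feats), value = TRUE)
    if (length(iso_cols) > 0) {
      mns <- sort(colMeans(feats[iso_cols]), decreasing = TRUE)
      top <- utils::head(mns, 3)
      lines <- c(lines, sprintf(
        "Top isoforms (cohort mean): %s",
        paste(sprintf("%s=%.2f%%", sub("^iso_", "", names(top)), top),
              collapse = ", ")))
    }
  }

  f <- file.path(dir, "differential.tsv")
  if (file.exists(f)) {
    dt <- utils::read.delim(f)
    for (cmp in unique(dt$comparison)) {
      sub <- dt[dt$comparison == cmp, ]
      lines <- c(lines, sprintf(
        "%s: %d/%d features significant (BH < 0.05): %s", cmp,
        sum(sub$sig), nrow(sub),
        paste(sub$feature[sub$sig], collapse = ", ")))
    }
  } else missing <- c(missing, "test")

  f <- file.path(dir, "classifier_report.json")
  if (file.exists(f)) {
    rep <- jsonlite::read_json(f)
    lines <- c(lines, sprintf(
      "SA vs Ctrl random forest: AUC = %.3f [%.3f; %.3f], sens %.0f%%, spec %.0f%%",
      rep$auc, rep$auc_ci$lower, rep$auc_ci$upper,
      100 * rep$sensitivity, 100 * rep$specificity))
  } else missing <- c(missing, "classify")

  if (length(lines) == 0) {
    lines <- "no stages completed"
  } else if (length(missing) > 0) {
    lines <- c(lines, sprintf("missing stages: %s",
                              paste(unique(missing), collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
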