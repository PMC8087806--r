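# Subject-level feature extraction: replicate profiles -> aggregated
# subject profile -> one shared feature space (site levels + isoform
# proportions) for the whole cohort. The analysis site set is fixed on the
# control-group mean profile so every sample lives in the same feature
# space; per-sample pass flags are still available via call_sites().

#' Compute per-subject editing features for a simulated cohort
#'
#' Uses the simulator's per-replicate pattern counts directly (the
#' error-free fast path; classifying error-free reads recovers exactly
#' these counts). Replicates are averaged with [aggregate_replicates()].
#' The analysis site set is the set of sites passing the detection
#' threshold on the control-group mean profile; the isoform set keeps
#' patterns whose control-group mean relative proportion is at least the
#' inclusion threshold.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param cfg A `site_calling_config`.
#' @return List: `features` (data.frame: subject_id, group, MADRS, IDSC30,
#'   `site_*` and `iso_*` columns), `site_calls` (control-mean site calls),
#'   `isoforms` (included isoform labels), `subject_profiles` (list).
#' @export
cohort_features <- function(cohort, cfg = site_calling_config()) {
  subj_profiles <- lapply(cohort$counts, function(cmat) {
    reps <- lapply(seq_len(ncol(cmat)), function(r) {
      profile_from_counts(cmat[, r], cfg)
    })
    aggregate_replicates(reps)
  })
  feature_space_and_table(subj_profiles, cohort$metadata, cohort$ref, cfg)
}

# shared by the counts path and the FASTQ path: given aggregated subject
# profiles, fix the feature space on the control mean and tabulate
feature_space_and_table <- function(subj_profiles, metadata, ref, cfg) {
  stopifnot(identical(names(subj_profiles), metadata$subject_id))
  all_sites <- ref$sites$label
  site_mat <- t(vapply(subj_profiles, site_level_from_isoforms,
                       setNames(numeric(length(all_sites)), all_sites),
                       site_labels = all_sites))

  is_ctrl <- metadata$group == "Ctrl"
  ref_group <- if (any(is_ctrl)) is_ctrl else rep(TRUE, nrow(metadata))
  ctrl_site_mean <- colMeans(site_mat[ref_group, , drop = FALSE])
  site_calls <- call_sites_pct(ctrl_site_mean, cfg)
  passing <- site_calls$label[site_calls$pass]

  iso_labs <- unique(unlist(lapply(subj_profiles,
                                   function(p) names(p$proportions))))
  iso_labs <- iso_labs[order(iso_labs != "NonEdited", nchar(iso_labs),
                             iso_labs)]
  iso_mat <- t(vapply(subj_profiles, function(p) {
    v <- setNames(numeric(length(iso_labs)), iso_labs)
    v[names(p$proportions)] <- p$proportions
    v
  }, setNames(numeric(length(iso_labs)), iso_labs)))
  ctrl_iso_mean <- colMeans(iso_mat[ref_group, , drop = FALSE])
  included <- iso_labs[ctrl_iso_mean >= cfg$isoform_threshold]

  features <- cbind(
    metadata[, c("subject_id", "group", "MADRS", "IDSC30")],
    as.data.frame(site_mat[, passing, drop = FALSE]) |>
      stats::setNames(paste0("site_", passing)),
    as.data.frame(iso_mat[, included, drop = FALSE]) |>
      stats::setNames(paste0("iso_", included))
  )
  rownames(features) <- NULL
  list(features = features, site_calls = site_calls,
       isoforms = included, subject_profiles = subj_profiles)
}

#' Quantify a cohort from FASTQ files on disk
#'
#' The full read-level path: per replicate, reads are aligned to the
#' amplicon and base counts taken; the analysis site set is fixed on the
#' control-group mean G-percentage profile; reads are then classified into
#' co-editing isoforms over that site set and replicates averaged.
#'
#' @param dir Directory holding `<subject>_rep<k>.fastq[.gz]` files and
#'   `metadata.tsv` as written by [simulate_cohort()].
#' @param ref A `reference_amplicon`.
#' @param cfg A `site_calling_config`.
#' @return As [cohort_features()].
#' @export
quantify_cohort_dir <- function(dir, ref = default_amplicon(),
                                cfg = site_calling_config()) {
  metadata <- utils::read.delim(file.path(dir, "metadata.tsv"),
                                stringsAsFactors = FALSE)
  aligned <- lapply(seq_len(nrow(metadata)), function(i) {
    files <- strsplit(metadata$files[i], ";", fixed = TRUE)[[1]]
    lapply(file.path(dir, files), function(f) align_reads(f, ref, cfg))
  })
  names(aligned) <- metadata$subject_id

  # pass 1: site percentages per subject (replicate-mean), control mean
  site_pct <- t(vapply(aligned, function(reps) {
    per_rep <- vapply(reps, function(a) {
      call_sites(count_bases(a, ref), ref, cfg)$G_pct
    }, numeric(nrow(ref$sites)))
    rowMeans(per_rep)
  }, numeric(nrow(ref$sites))))
  colnames(site_pct) <- ref$sites$label
  is_ctrl <- metadata$group == "Ctrl"
  ref_group <- if (any(is_ctrl)) is_ctrl else rep(TRUE, nrow(metadata))
  site_calls <- call_sites_pct(colMeans(site_pct[ref_group, , drop = FALSE]),
                               cfg)
  passing <- site_calls$label[site_calls$pass]

  # pass 2: isoform enumeration over the fixed site set
  subj_profiles <- lapply(aligned, function(reps) {
    aggregate_replicates(lapply(reps, function(a) {
      enumerate_isoforms(a, passing, ref, cfg)
    }))
  })
  out <- feature_space_and_table(subj_profiles, metadata, ref, cfg)
  out$site_calls <- site_calls
  out
}
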