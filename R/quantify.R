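# Quantification: amplicon alignment, per-position base counts, the
# G-percentage editing level, strict site calling, and per-read co-editing
# isoform enumeration. Editing level at a position is
#   100 * G / (G + A)
# over aligned reads; C/T/N calls enter neither numerator nor denominator.
# A candidate position passes site calling when its level is strictly
# above the detection threshold (default 0.1%). An isoform is the set of
# passing sites carrying 'G' on one read; its relative proportion is the
# percentage of classified reads with exactly that pattern.

#' Site-calling configuration
#'
#' @param detection_threshold Editing percentage above which (strictly) a
#'   candidate position is called a site. Default 0.1.
#' @param isoform_threshold Relative proportion (%) below which an isoform
#'   is flagged below-threshold (it stays in the table). Default 0.1.
#' @param exclusion_note Reporting-only level (%) under which positions are
#'   described as background. Default 0.05.
#' @param max_mismatches Alignment acceptance cap on mismatches outside
#'   candidate offsets. Default 5.
#' @return A list of class `site_calling_config`.
#' @export
site_calling_config <- function(detection_threshold = 0.1,
                                isoform_threshold = 0.1,
                                exclusion_note = 0.05,
                                max_mismatches = 5) {
  stopifnot(detection_threshold > 0, detection_threshold < 100,
            isoform_threshold > 0, isoform_threshold < 100)
  structure(list(detection_threshold = detection_threshold,
                 isoform_threshold = isoform_threshold,
                 exclusion_note = exclusion_note,
                 max_mismatches = max_mismatches),
            class = "site_calling_config")
}

#' Read a FASTQ file into a character vector of reads
#'
#' @param path FASTQ path (gz-transparent).
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}

as_read_vector <- function(reads) {
  if (inherits(reads, "read_set")) return(reads$reads)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    return(read_fastq(reads))
  }
  as.character(reads)
}

#' Anchored amplicon alignment
#'
#' Every read is compared ungapped at offset 0 against the full amplicon.
#' A read is accepted when its length matches the reference and its
#' Hamming distance outside candidate offsets is at most the configured
#' cap; otherwise it is discarded with a counted reason.
#'
#' @param reads `read_set`, character vector, or FASTQ path.
#' @param ref A `reference_amplicon`.
#' @param cfg A `site_calling_config` (uses `max_mismatches`).
#' @return List of class `aligned_reads`: `reads` (accepted, character),
#'   `discarded` (named counts: `length_mismatch`, `too_many_mismatches`).
#' @export
align_reads <- function(reads, ref, cfg = site_calling_config()) {
  reads <- as_read_vector(reads)
  if (length(reads) == 0) stop("no reads to align")
  L <- nchar(ref$sequence)
  len_ok <- nchar(reads) == L
  kept <- reads[len_ok]
  n_len_bad <- sum(!len_ok)

  mism <- integer(length(kept))
  if (length(kept) > 0) {
    ref_chars <- strsplit(ref$sequence, "")[[1]]
    non_cand <- setdiff(seq_len(L), ref$sites$offset + 1L)
    for (j in non_cand) {
      mism <- mism + (substr(kept, j, j) != ref_chars[j])
    }
  }
  acc <- mism <= cfg$max_mismatches
  structure(list(
    reads = kept[acc],
    discarded = c(length_mismatch = n_len_bad,
                  too_many_mismatches = sum(!acc))
  ), class = "aligned_reads")
}

#' Per-position base counts over aligned reads
#'
#' @param aligned An `aligned_reads` object (or character vector of
#'   equal-length reads).
#' @param ref A `reference_amplicon`.
#' @return data.frame of class `base_count_table`: `offset` (0-based),
#'   `A`, `C`, `G`, `T`, `other`, `depth`; attribute `total_reads`.
#' @export
count_bases <- function(aligned, ref) {
  reads <- if (inherits(aligned, "aligned_reads")) aligned$reads else aligned
  if (length(reads) == 0) stop("count_bases needs at least one aligned read")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(reads))
  L <- nchar(ref$sequence)
  get_row <- function(b) {
    if (b %in% rownames(cm)) as.integer(cm[b, ]) else integer(L)
  }
  A <- get_row("A"); C <- get_row("C"); G <- get_row("G"); T <- get_row("T")
  other <- length(reads) - (A + C + G + T)
  out <- data.frame(offset = seq_len(L) - 1L, A = A, C = C, G = G, T = T,
                    other = other, depth = length(reads))
  attr(out, "total_reads") <- length(reads)
  class(out) <- c("base_count_table", "data.frame")
  out
}

#' Editing percentage at a position
#'
#' `100 * G / (G + A)`; other base calls are excluded from both numerator
#' and denominator. Undefined (NA) when no A or G call is present — never
#' reported as zero.
#'
#' @param g,a Counts of G and A calls at the position (vectorised).
#' @return Percentage in `[0, 100]`, or `NA_real_` where `g + a == 0`.
#' @export
editing_percentage <- function(g, a) {
  ifelse(g + a == 0, NA_real_, 100 * g / (g + a))
}

#' Call editing sites from a base-count table
#'
#' Every candidate A position receives a call; `pass` is strict
#' (percentage > detection threshold).
#'
#' @param table A `base_count_table`.
#' @param ref A `reference_amplicon`.
#' @param cfg A `site_calling_config`.
#' @return data.frame: `label`, `offset` (0-based), `position` (1-based),
#'   `G_pct`, `pass`.
#' @export
call_sites <- function(table, ref, cfg = site_calling_config()) {
  idx <- match(ref$sites$offset, table$offset)
  pct <- editing_percentage(table$G[idx], table$A[idx])
  data.frame(
    label = ref$sites$label,
    offset = ref$sites$offset,
    position = ref$sites$offset + 1L,
    G_pct = pct,
    pass = !is.na(pct) & pct > cfg$detection_threshold,
    stringsAsFactors = FALSE
  )
}

#' Site calls from aggregated editing percentages
#'
#' Variant of [call_sites()] for percentages already averaged across
#' replicates or subjects (e.g. the control-group mean profile used to fix
#' the cohort feature space).
#'
#' @param pct Named numeric vector of editing percentages per site label.
#' @param cfg A `site_calling_config`.
#' @return data.frame: `label`, `G_pct`, `pass`.
#' @export
call_sites_pct <- function(pct, cfg = site_calling_config()) {
  data.frame(label = names(pct), G_pct = unname(pct),
             pass = !is.na(pct) & pct > cfg$detection_threshold,
             stringsAsFactors = FALSE)
}

# canonical label for a set of site letters (in amplicon order)
isoform_label <- function(sites, ref) {
  if (length(sites) == 0) return("NonEdited")
  paste(ref$sites$label[ref$sites$label %in% sites], collapse = "")
}

new_isoform_profile <- function(proportions, classified, discarded,
                                isoform_threshold = 0.1) {
  structure(list(
    proportions = proportions,
    classified = classified,
    discarded = discarded,
    below_threshold = proportions < isoform_threshold,
    isoform_threshold = isoform_threshold
  ), class = "isoform_profile")
}

#' Enumerate per-read co-editing isoforms
#'
#' Classifies each aligned read by the set of passing sites at which it
#' carries 'G'. Reads with a C/T/N call at any passing site are excluded
#' from classification (keeping the denominator consistent with the
#' site-level G/(G+A) formula) and counted. Proportions are percentages of
#' classified reads; patterns under the inclusion threshold are flagged
#' but kept in the table.
#'
#' @param aligned `aligned_reads` (or character vector).
#' @param sites Site-call data.frame from [call_sites()]; only rows with
#'   `pass == TRUE` define the pattern space. May also be a character
#'   vector of passing site labels.
#' @param ref A `reference_amplicon`.
#' @param cfg A `site_calling_config`.
#' @return An `isoform_profile`: `proportions` (named percentages summing
#'   to 100 over observed patterns), `classified`, `discarded`,
#'   `below_threshold` flags.
#' @export
enumerate_isoforms <- function(aligned, sites, ref,
                               cfg = site_calling_config()) {
  reads <- if (inherits(aligned, "aligned_reads")) aligned$reads else aligned
  if (length(reads) == 0) stop("no aligned reads to classify")
  if (is.data.frame(sites)) sites <- sites$label[sites$pass]
  sites <- ref$sites$label[ref$sites$label %in% sites]

  if (length(sites) == 0) {
    return(new_isoform_profile(c(NonEdited = 100), length(reads), 0L,
                               cfg$isoform_threshold))
  }
  offs <- ref$sites$offset[match(sites, ref$sites$label)] + 1L
  base_mat <- vapply(offs, function(j) substr(reads, j, j),
                     character(length(reads)))
  if (length(reads) == 1L) base_mat <- matrix(base_mat, nrow = 1)
  ok <- rowSums(base_mat != "A" & base_mat != "G") == 0
  n_discarded <- sum(!ok)
  base_mat <- base_mat[ok, , drop = FALSE]
  if (nrow(base_mat) == 0) stop("all reads discarded at passing sites")

  key <- apply(base_mat == "G", 1, function(v) {
    if (!any(v)) "NonEdited" else paste(sites[v], collapse = "")
  })
  tab <- table(key)
  prop <- 100 * as.numeric(tab) / sum(tab)
  names(prop) <- names(tab)
  # order: NonEdited first, then by pattern size and site order
  ord <- order(names(prop) != "NonEdited", nchar(names(prop)), names(prop))
  new_isoform_profile(prop[ord], classified = sum(tab),
                      discarded = n_discarded, cfg$isoform_threshold)
}

#' Isoform profile directly from per-pattern read counts
#'
#' Error-free fast path used when the simulator's multinomial pattern
#' counts are analysed without a FASTQ round trip; classification of
#' error-free reads recovers exactly these counts.
#'
#' @param counts Named integer vector (isoform label -> read count).
#' @param cfg A `site_calling_config`.
#' @return An `isoform_profile`.
#' @export
profile_from_counts <- function(counts, cfg = site_calling_config()) {
  total <- sum(counts)
  if (total == 0) stop("no reads in counts")
  prop <- 100 * counts / total
  new_isoform_profile(prop[prop > 0 | names(prop) == "NonEdited"],
                      classified = total, discarded = 0L,
                      cfg$isoform_threshold)
}

#' Site levels from an isoform profile
#'
#' The relative proportion of editing at a site is the sum of proportions
#' of all isoforms whose pattern contains that site.
#'
#' @param profile An `isoform_profile`.
#' @param site_labels Optional site universe; defaults to the letters
#'   appearing in the profile.
#' @return Named numeric vector of site-level percentages.
#' @export
site_level_from_isoforms <- function(profile, site_labels = NULL) {
  p <- profile$proportions
  if (is.null(site_labels)) {
    site_labels <- sort(unique(unlist(lapply(names(p), isoform_sites))))
  }
  out <- setNames(numeric(length(site_labels)), site_labels)
  for (lab in names(p)) {
    for (s in isoform_sites(lab)) {
      if (s %in% site_labels) out[s] <- out[s] + p[[lab]]
    }
  }
  out
}

#' Average isoform profiles across technical replicates
#'
#' Unweighted arithmetic mean of per-replicate relative proportions
#' (replicates are independent library preparations; pooling reads would
#' weight them by depth).
#'
#' @param profiles List of `isoform_profile` objects.
#' @return An `isoform_profile` with summed read-count bookkeeping.
#' @export
aggregate_replicates <- function(profiles) {
  if (length(profiles) == 0) stop("no replicate profiles to aggregate")
  labs <- unique(unlist(lapply(profiles, function(p) names(p$proportions))))
  mat <- vapply(profiles, function(p) {
    v <- setNames(numeric(length(labs)), labs)
    v[names(p$proportions)] <- p$proportions
    v
  }, setNames(numeric(length(labs)), labs))
  if (length(labs) == 1L) mat <- matrix(mat, nrow = 1,
                                        dimnames = list(labs, NULL))
  thr_level <- profiles[[1]]$isoform_threshold
  new_isoform_profile(rowMeans(mat),
                      classified = sum(vapply(profiles, `[[`, numeric(1),
                                              "classified")),
                      discarded = sum(vapply(profiles, `[[`, numeric(1),
                                             "discarded")),
                      thr_level)
}

#' @export
print.isoform_profile <- function(x, ...) {
  cat("Isoform profile (", x$classified, " classified reads, ",
      x$discarded, " discarded)\n", sep = "")
  df <- data.frame(isoform = names(x$proportions),
                   proportion_pct = round(unname(x$proportions), 4),
                   below_threshold = unname(x$below_threshold))
  print(df, row.names = FALSE)
  invisible(x)
}
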