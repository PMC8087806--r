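# Read and cohort simulator. Reads are full-length error-only amplicon
# copies: a transcript drawn with co-editing pattern S carries 'G' at the
# offsets of the sites in S and the reference base everywhere else, then
# independent per-base substitution error is applied. Each subject gets a
# lognormal editing-activity factor scaling the group's whole edited mass
# (the concerted island-wide modulation that makes all site levels
# positively correlated across subjects), then an isoform probability
# vector drawn from a Dirichlet around that scaled mean; technical
# replicates are independent multinomial draws from the subject vector.

#' Simulate amplicon reads from an isoform distribution
#'
#' @param dist An `isoform_distribution`.
#' @param ref A `reference_amplicon`.
#' @param depth Number of reads to draw (>= 1).
#' @param error_rate Per-base substitution error probability (uniform over
#'   the three alternative bases).
#' @param seed Optional integer; when given the draw is reproducible.
#' @param counts Optional named integer vector of per-isoform read counts;
#'   when supplied the multinomial draw is skipped and exactly these reads
#'   are generated (names must match `names(dist)` semantics).
#' @return Object of class `read_set`: list with `reads` (character
#'   vector), `isoform` (true pattern per read, pre-error) and `ref`.
#' @export
simulate_reads <- function(dist, ref, depth, error_rate = 0, seed = NULL,
                           counts = NULL) {
  if (is.null(counts)) {
    stopifnot(depth >= 1)
    dist <- isoform_distribution(unclass(dist), ref = ref)
  } else {
    dist <- isoform_distribution(unclass(dist), ref = ref)
    stopifnot(all(names(counts) %in% names(dist)))
    depth <- sum(counts)
  }
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  labs <- names(dist)
  if (is.null(counts)) {
    n_per <- as.integer(stats::rmultinom(1, depth, unclass(dist)))
  } else {
    n_per <- as.integer(counts[labs])
    n_per[is.na(n_per)] <- 0L
  }

  # one template string per isoform, then replicate
  templates <- vapply(labs, function(lab) {
    s <- ref$sequence
    for (site in isoform_sites(lab)) {
      off <- ref$sites$offset[ref$sites$label == site]
      substr(s, off + 1L, off + 1L) <- "G"
    }
    s
  }, character(1))
  reads <- rep(templates, times = n_per)
  iso <- rep(labs, times = n_per)

  # shuffle so replicate files are not sorted by pattern
  ord <- sample.int(length(reads))
  reads <- reads[ord]
  iso <- iso[ord]

  if (error_rate > 0 && length(reads) > 0) {
    L <- nchar(ref$sequence)
    n_cells <- length(reads) * L
    n_err <- stats::rbinom(1, n_cells, error_rate)
    if (n_err > 0) {
      cells <- sample(n_cells, n_err)
      ridx <- ((cells - 1L) %/% L) + 1L
      pos <- ((cells - 1L) %% L) + 1L
      for (k in seq_len(n_err)) {
        cur <- substr(reads[ridx[k]], pos[k], pos[k])
        alt <- setdiff(c("A", "C", "G", "T"), cur)
        substr(reads[ridx[k]], pos[k], pos[k]) <- sample(alt, 1)
      }
    }
  }

  structure(list(reads = reads, isoform = iso, ref = ref),
            class = "read_set")
}

#' Write a read set as FASTQ (4-line records, Phred+33, constant Q37)
#'
#' @param rs A `read_set`.
#' @param path Output file path (plain text; `.gz` paths are compressed).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  n <- length(rs$reads)
  qual <- strrep("F", nchar(rs$ref$sequence))  # 'F' = Q37 in Phred+33
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (n > 0) {
    lines <- character(4L * n)
    lines[seq(1, 4 * n, 4)] <- sprintf("@%s_read%06d", rs$ref$name, seq_len(n))
    lines[seq(2, 4 * n, 4)] <- rs$reads
    lines[seq(3, 4 * n, 4)] <- "+"
    lines[seq(4, 4 * n, 4)] <- qual
    writeLines(lines, con)
  }
  invisible(path)
}

#' Simulate clinician-rated severity scores
#'
#' MADRS and IDS-C30 are drawn from a shared latent severity factor so
#' their correlation hits a configurable target, then rounded to integers
#' and clipped at zero.
#'
#' @param n Number of subjects.
#' @param madrs_mean,madrs_sd MADRS moments.
#' @param idsc_mean,idsc_sd IDS-C30 moments.
#' @param r2 Target squared correlation between the two scales.
#' @return data.frame with integer columns `MADRS`, `IDSC30`.
#' @export
simulate_severity_scores <- function(n, madrs_mean, madrs_sd,
                                     idsc_mean, idsc_sd, r2 = 0.90) {
  stopifnot(r2 >= 0, r2 <= 1)
  rho <- sqrt(r2)
  z <- stats::rnorm(n)
  e1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  m <- madrs_mean + madrs_sd * (sqrt(rho) * z + sqrt(1 - rho) * e1)
  i <- idsc_mean + idsc_sd * (sqrt(rho) * z + sqrt(1 - rho) * e2)
  data.frame(MADRS = pmax(0L, as.integer(round(m))),
             IDSC30 = pmax(0L, as.integer(round(i))))
}

#' Default cohort configuration
#'
#' Group sizes follow the recruited cohort (99 controls, 101 depressed
#' non-attempters, 84 suicide attempters); the patient groups' edited mass
#' is scaled down (0.7x for DEP, 0.6x for SA) with the released probability
#' moved to the non-edited isoform. Severity-scale moments are the
#' cohort's descriptive statistics; the two scales share a latent factor
#' giving a squared correlation of 0.90.
#'
#' @param n_ctrl,n_dep,n_sa Group sizes.
#' @param control_dist Control-group `isoform_distribution`.
#' @param dep_factor,sa_factor Multipliers applied to the edited mass for
#'   the patient groups.
#' @param concentration Dirichlet concentration for subject-level
#'   pattern jitter (larger = less between-subject spread).
#' @param activity_sdlog SD (log scale) of the subject-level editing
#'   activity factor: a lognormal multiplier (mean 1) applied to the whole
#'   edited mass before the Dirichlet draw. This shared factor moves all
#'   sites of the island in concert, giving the strong positive
#'   inter-site correlation across subjects; it is mirrored by the
#'   non-edited isoform. Default 0.25.
#' @param reads_per_replicate Sequencing depth per technical replicate.
#' @param replicates Technical replicates per subject.
#' @param error_rate Per-base substitution error rate (must be <= 0.05).
#' @param severity_r2 Target squared correlation of MADRS and IDS-C30.
#' @param dep_dist,sa_dist Optional explicit patient-group
#'   `isoform_distribution`s; when given they override the
#'   `dep_factor`/`sa_factor` scaling (used e.g. to place a group effect
#'   on a subset of isoforms).
#' @param seed Base random seed.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_ctrl = 99, n_dep = 101, n_sa = 84,
                          control_dist = default_control_distribution(),
                          dep_factor = 0.7, sa_factor = 0.6,
                          concentration = 2000, activity_sdlog = 0.25,
                          reads_per_replicate = 2000, replicates = 5,
                          error_rate = 4e-4, severity_r2 = 0.90,
                          dep_dist = NULL, sa_dist = NULL,
                          seed = 1L) {
  cfg <- list(
    n = c(Ctrl = as.integer(n_ctrl), DEP = as.integer(n_dep),
          SA = as.integer(n_sa)),
    dist = list(
      Ctrl = control_dist,
      DEP = if (is.null(dep_dist)) {
        scale_edited_mass(control_dist, dep_factor)
      } else dep_dist,
      SA = if (is.null(sa_dist)) {
        scale_edited_mass(control_dist, sa_factor)
      } else sa_dist
    ),
    concentration = concentration,
    activity_sdlog = activity_sdlog,
    reads_per_replicate = as.integer(reads_per_replicate),
    replicates = as.integer(replicates),
    error_rate = error_rate,
    severity = list(
      Ctrl = c(madrs_mean = 0.65, madrs_sd = 1.25,
               idsc_mean = 2.01, idsc_sd = 2.46),
      DEP = c(madrs_mean = 28.99, madrs_sd = 9.55,
              idsc_mean = 34.87, idsc_sd = 10.02),
      SA = c(madrs_mean = 23.94, madrs_sd = 10.99,
             idsc_mean = 32.73, idsc_sd = 12.18),
      r2 = severity_r2
    ),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$n < 0)) stop("group sizes must be >= 0")
  if (sum(cfg$n) == 0) stop("cohort must contain at least one subject")
  if (cfg$error_rate < 0 || cfg$error_rate > 0.05) {
    stop("error_rate must be in [0, 0.05]")
  }
  if (cfg$replicates < 1) stop("replicates must be >= 1")
  if (cfg$concentration <= 0) stop("concentration must be > 0")
  if (cfg$activity_sdlog < 0) stop("activity_sdlog must be >= 0")
  if (cfg$reads_per_replicate < 1) stop("reads_per_replicate must be >= 1")
  invisible(cfg)
}

# Dirichlet draw around a mean vector with concentration c; components with
# zero mean stay exactly zero.
rdirichlet_mean <- function(mean_vec, concentration) {
  alpha <- concentration * mean_vec
  g <- numeric(length(mean_vec))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
  out <- g / sum(g)
  names(out) <- names(mean_vec)
  out
}

#' Simulate a cohort with replicate structure and ground truth
#'
#' Draws subject-specific isoform probability vectors (Dirichlet around the
#' group mean), per-replicate multinomial read-pattern counts, and clinical
#' metadata. When `out_dir` is given, full FASTQ files (one per subject and
#' replicate, expanded from exactly those counts, with substitution errors
#' applied) plus metadata and truth TSVs are written there.
#'
#' @param config A `cohort_config`.
#' @param out_dir Optional directory for FASTQ/TSV output.
#' @param ref Reference amplicon (defaults to [default_amplicon()]).
#' @return Object of class `cohort`: list with `metadata` (subject_id,
#'   group, MADRS, IDSC30, files), `truth` (per subject x replicate true
#'   proportions and per-site truth), `counts` (list of isoform x replicate
#'   count matrices per subject), `subject_probs`, `ref`, `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL, ref = default_amplicon()) {
  validate_cohort_config(config)
  set.seed(config$seed)

  groups <- rep(names(config$n), times = config$n)
  n_total <- length(groups)
  subject_id <- sprintf("S%03d", seq_len(n_total))

  # union of isoform labels across groups, in control order first
  labs <- unique(unlist(lapply(config$dist, names)))

  sev <- do.call(rbind, lapply(names(config$n), function(g) {
    p <- config$severity[[g]]
    simulate_severity_scores(config$n[[g]], p["madrs_mean"], p["madrs_sd"],
                             p["idsc_mean"], p["idsc_sd"],
                             r2 = config$severity$r2)
  }))

  subject_probs <- matrix(0, nrow = n_total, ncol = length(labs),
                          dimnames = list(subject_id, labs))
  counts <- vector("list", n_total)
  names(counts) <- subject_id
  truth_rows <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    gdist <- config$dist[[groups[i]]]
    if (config$activity_sdlog > 0) {
      act <- stats::rlnorm(1, meanlog = -config$activity_sdlog^2 / 2,
                           sdlog = config$activity_sdlog)
      # cap so the scaled edited mass stays a valid probability
      edited_mass <- sum(unclass(gdist)[names(gdist) != "NonEdited"])
      act <- min(act, 0.99 / edited_mass)
      gdist <- scale_edited_mass(gdist, act)
    }
    mean_vec <- setNames(numeric(length(labs)), labs)
    mean_vec[names(gdist)] <- unclass(gdist)
    p_subj <- rdirichlet_mean(mean_vec, config$concentration)
    subject_probs[i, ] <- p_subj

    cmat <- stats::rmultinom(config$replicates, config$reads_per_replicate,
                             p_subj)
    rownames(cmat) <- labs
    colnames(cmat) <- sprintf("rep%d", seq_len(config$replicates))
    counts[[i]] <- cmat

    truth_rows[[i]] <- data.frame(
      subject_id = subject_id[i], group = groups[i],
      replicate = colnames(cmat),
      matrix(p_subj, nrow = config$replicates, ncol = length(labs),
             byrow = TRUE),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }

  truth <- do.call(rbind, truth_rows)
  names(truth)[-(1:3)] <- labs
  site_truth <- t(vapply(seq_len(n_total), function(i) {
    sf <- setNames(numeric(nrow(ref$sites)), ref$sites$label)
    for (lab in labs) {
      for (s in isoform_sites(lab)) {
        sf[s] <- sf[s] + subject_probs[i, lab]
      }
    }
    sf
  }, setNames(numeric(nrow(ref$sites)), ref$sites$label)))
  rownames(site_truth) <- subject_id

  metadata <- data.frame(
    subject_id = subject_id, group = groups,
    MADRS = sev$MADRS, IDSC30 = sev$IDSC30,
    stringsAsFactors = FALSE
  )
  metadata$files <- vapply(subject_id, function(sid) {
    paste(sprintf("%s_rep%d.fastq", sid, seq_len(config$replicates)),
          collapse = ";")
  }, character(1))

  cohort <- structure(
    list(metadata = metadata, truth = truth, site_truth = site_truth,
         counts = counts, subject_probs = subject_probs,
         ref = ref, config = config),
    class = "cohort"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_total)) {
      for (r in seq_len(config$replicates)) {
        rs <- simulate_reads(config$dist[[groups[i]]], ref,
                             depth = config$reads_per_replicate,
                             error_rate = config$error_rate,
                             counts = counts[[i]][, r])
        write_fastq(rs, file.path(out_dir,
                                  sprintf("%s_rep%d.fastq", subject_id[i], r)))
      }
    }
    utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- cbind(truth,
                as.data.frame(site_truth[truth$subject_id, , drop = FALSE]))
    utils::write.table(tr, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$metadata), "subjects (",
      paste(sprintf("%s=%d", names(table(x$metadata$group)),
                    as.integer(table(x$metadata$group))), collapse = ", "),
      ");", x$config$replicates, "replicates x",
      x$config$reads_per_replicate, "reads\n")
  invisible(x)
}
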