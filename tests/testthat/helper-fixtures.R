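# Shared fixtures: all built in code at test time.

REF <- default_amplicon()

# build a read carrying 'G' at the given site labels (independent of
# simulate_reads; used as a hand-construction oracle)
read_with_sites <- function(sites, ref = REF) {
  s <- ref$sequence
  for (lab in sites) {
    off <- ref$sites$offset[ref$sites$label == lab]
    substr(s, off + 1L, off + 1L) <- "G"
  }
  s
}

# mutate a read at the given 1-based positions to the given bases
mutate_read <- function(s, positions, bases) {
  for (k in seq_along(positions)) {
    substr(s, positions[k], positions[k]) <- bases[k]
  }
  s
}

# brute-force per-read isoform classifier: loops over reads and passing
# sites, character by character (the independent oracle for the pipeline)
brute_force_profile <- function(reads, passing, ref = REF) {
  offs <- ref$sites$offset[match(passing, ref$sites$label)] + 1L
  keys <- character(0)
  discarded <- 0L
  for (r in reads) {
    bases <- vapply(offs, function(j) substr(r, j, j), character(1))
    if (any(!bases %in% c("A", "G"))) {
      discarded <- discarded + 1L
      next
    }
    edited <- passing[bases == "G"]
    keys <- c(keys, if (length(edited) == 0) "NonEdited"
              else paste(edited, collapse = ""))
  }
  list(proportions = 100 * table(keys) / length(keys),
       discarded = discarded)
}

# small cohort config for fast tests
tiny_cohort_config <- function(...) {
  cohort_config(n_ctrl = 12, n_dep = 10, n_sa = 10,
                reads_per_replicate = 400, replicates = 2, ...)
}
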