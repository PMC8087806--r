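test_that("anchored alignment accepts the reference and applies the cap", {
  a <- align_reads(REF$sequence, REF)
  expect_length(a$reads, 1)
  expect_equal(sum(a$discarded), 0)

  # 5 mismatches at non-candidate offsets: accepted; 6: discarded
  non_cand <- setdiff(seq_len(225), REF$sites$offset + 1L)
  flip <- function(pos) {
    vapply(pos, function(j) {
      setdiff(c("A", "C", "G", "T"),
              substr(REF$sequence, j, j))[1]
    }, character(1))
  }
  r5 <- mutate_read(REF$sequence, non_cand[1:5], flip(non_cand[1:5]))
  r6 <- mutate_read(REF$sequence, non_cand[1:6], flip(non_cand[1:6]))
  a <- align_reads(c(r5, r6), REF)
  expect_length(a$reads, 1)
  expect_equal(unname(a$discarded["too_many_mismatches"]), 1)

  # wrong length is discarded, not fatal
  a <- align_reads(c(REF$sequence, substr(REF$sequence, 1, 100)), REF)
  expect_equal(unname(a$discarded["length_mismatch"]), 1)

  # generator round trip: error-free reads all align
  rs <- simulate_reads(default_control_distribution(), REF, 100,
                       error_rate = 0, seed = 2)
  a <- align_reads(rs, REF)
  expect_length(a$reads, 100)
  expect_equal(sum(a$discarded), 0)
})

test_that("base counts tally nucleotides per position and conserve reads", {
  off_b <- REF$sites$offset[REF$sites$label == "B"]

  bt <- count_bases(rep(REF$sequence, 10), REF)
  expect_equal(bt$A[bt$offset == off_b], 10)
  expect_equal(bt$G[bt$offset == off_b], 0)

  reads <- c(rep(REF$sequence, 8), rep(read_with_sites("B"), 2))
  bt <- count_bases(reads, REF)
  expect_equal(bt$A[bt$offset == off_b], 8)
  expect_equal(bt$G[bt$offset == off_b], 2)

  # conservation: counts summed over offsets = reads x length
  expect_equal(sum(bt$A + bt$C + bt$G + bt$T + bt$other), 10 * 225)
  expect_true(all(bt$A + bt$C + bt$G + bt$T + bt$other <= bt$depth))
})

test_that("editing percentage is G/(G+A)*100 with non-A/G calls excluded", {
  expect_equal(editing_percentage(20, 80), 20.0)
  expect_equal(editing_percentage(0, 50), 0.0)
  expect_equal(editing_percentage(1, 999), 0.1)  # C calls play no role
  expect_true(is.na(editing_percentage(0, 0)))   # undefined, never 0
  expect_equal(editing_percentage(c(20, 0), c(80, 0)), c(20, NA_real_))
})

test_that("site calling is strictly above the threshold", {
  # exactly 0.1%: 1 G among 1000 A+G -> not a site
  reads <- c(rep(REF$sequence, 999), read_with_sites("B"))
  sc <- call_sites(count_bases(reads, REF), REF)
  expect_equal(sc$G_pct[sc$label == "B"], 0.1)
  expect_false(sc$pass[sc$label == "B"])

  # one read more and it passes
  reads <- c(reads, read_with_sites("B"))
  sc <- call_sites(count_bases(reads, REF), REF)
  expect_true(sc$pass[sc$label == "B"])

  # all-reference reads: no passing site
  sc <- call_sites(count_bases(rep(REF$sequence, 50), REF), REF)
  expect_equal(sum(sc$pass), 0)

  expect_equal(sum(call_sites_pct(c(B = 0.1, C = 0.11))$pass), 1)
})

test_that("isoform enumeration matches direct hand enumeration", {
  reads <- c(rep(REF$sequence, 6), rep(read_with_sites("B"), 3),
             read_with_sites(c("B", "C")))
  prof <- enumerate_isoforms(reads, c("B", "C"), REF)
  expect_equal(prof$proportions,
               c(NonEdited = 60, B = 30, BC = 10))
  expect_equal(prof$classified, 10)
  expect_equal(prof$discarded, 0)
  expect_equal(sum(prof$proportions), 100, tolerance = 1e-6)

  # derived site levels: B = 40, C = 10 (site = sum over patterns)
  sl <- site_level_from_isoforms(prof)
  expect_equal(unname(sl["B"]), 40)
  expect_equal(unname(sl["C"]), 10)

  # a read with 'T' at a passing site is excluded and counted
  off_b <- REF$sites$offset[REF$sites$label == "B"] + 1L
  bad <- mutate_read(REF$sequence, off_b, "T")
  prof <- enumerate_isoforms(c(reads, bad), c("B", "C"), REF)
  expect_equal(prof$discarded, 1)
  expect_equal(prof$classified, 10)

  # all-reference reads: non-edited at 100%
  prof <- enumerate_isoforms(rep(REF$sequence, 5), c("B"), REF)
  expect_equal(prof$proportions, c(NonEdited = 100))
  # no passing sites at all: single non-edited pattern
  prof <- enumerate_isoforms(rep(REF$sequence, 5), character(0), REF)
  expect_equal(prof$proportions, c(NonEdited = 100))
})

test_that("recovered proportions match the multinomial truth at depth 20000", {
  truth <- c(NonEdited = 0.7, B = 0.25, BC = 0.05)
  rs <- simulate_reads(isoform_distribution(truth), REF, 20000,
                       error_rate = 0, seed = 21)
  a <- align_reads(rs, REF)
  prof <- enumerate_isoforms(a, c("B", "C"), REF)
  for (lab in names(truth)) {
    se <- sqrt(truth[lab] * (1 - truth[lab]) / 20000)
    expect_lt(abs(prof$proportions[lab] / 100 - truth[lab]), 4 * se)
  }
})

test_that("pipeline output equals the brute-force read classifier", {
  rs <- simulate_reads(default_control_distribution(), REF, 3000,
                       error_rate = 0, seed = 33)
  a <- align_reads(rs, REF)
  passing <- c("B", "C", "D", "E", "F")
  prof <- enumerate_isoforms(a, passing, REF)
  oracle <- brute_force_profile(a$reads, passing)
  expect_equal(prof$discarded, oracle$discarded)
  for (lab in names(prof$proportions)) {
    expect_equal(unname(prof$proportions[lab]),
                 unname(as.numeric(oracle$proportions[lab])),
                 tolerance = 1e-9)
  }
  # and equals the generator's own per-read pattern tally
  gen_tally <- 100 * table(rs$isoform) / length(rs$isoform)
  for (lab in names(prof$proportions)) {
    expect_equal(unname(prof$proportions[lab]),
                 unname(as.numeric(gen_tally[lab])))
  }
})

test_that("site levels from count table and from isoforms agree", {
  rs <- simulate_reads(default_control_distribution(), REF, 20000,
                       error_rate = 0, seed = 8)
  a <- align_reads(rs, REF)
  sc <- call_sites(count_bases(a, REF), REF)
  prof <- enumerate_isoforms(a, sc, REF)
  sl <- site_level_from_isoforms(prof)
  for (lab in names(sl)) {
    # error-free: identical denominators, so the two routes coincide
    expect_equal(unname(sl[lab]), sc$G_pct[sc$label == lab],
                 tolerance = 1e-9)
  }
})

test_that("replicate aggregation averages proportions", {
  p1 <- profile_from_counts(c(NonEdited = 60, B = 40))
  p2 <- profile_from_counts(c(NonEdited = 80, B = 20))
  expect_equal(aggregate_replicates(list(p1, p1))$proportions,
               p1$proportions)  # idempotence
  agg <- aggregate_replicates(list(p1, p2))
  expect_equal(agg$proportions, c(NonEdited = 70, B = 30))
  expect_equal(sum(agg$proportions), 100, tolerance = 1e-6)
  expect_error(aggregate_replicates(list()), "no replicate")

  # replicates with disjoint pattern support: missing patterns count as 0
  p3 <- profile_from_counts(c(NonEdited = 50, BC = 50))
  agg <- aggregate_replicates(list(p1, p3))
  expect_equal(agg$proportions[c("NonEdited", "B", "BC")],
               c(NonEdited = 55, B = 20, BC = 25))
})

test_that("aggregating five replicates reduces estimation error", {
  set.seed(17)
  p_true <- 0.25
  depth <- 500
  err_agg <- numeric(100)
  err_one <- numeric(100)
  beats <- 0
  for (b in 1:100) {
    reps <- lapply(1:5, function(r) {
      n_b <- rbinom(1, depth, p_true)
      profile_from_counts(c(NonEdited = depth - n_b, B = n_b))
    })
    est_agg <- aggregate_replicates(reps)$proportions["B"] / 100
    est_one <- reps[[1]]$proportions["B"] / 100
    err_agg[b] <- abs(est_agg - p_true)
    err_one[b] <- abs(est_one - p_true)
    beats <- beats + (err_agg[b] < err_one[b])
  }
  expect_lt(mean(err_agg), mean(err_one))
  expect_gte(beats, 60)
})

test_that("changes in the dominant pattern mirror the non-edited pattern", {
  # vary only the {B} mass against the non-edited mass: estimated changes
  # are equal in magnitude and opposite in sign (within sampling error)
  d1 <- isoform_distribution(c(NonEdited = 0.80, B = 0.20))
  d2 <- isoform_distribution(c(NonEdited = 0.88, B = 0.12))
  est <- function(d, seed) {
    rs <- simulate_reads(d, REF, 20000, error_rate = 0, seed = seed)
    prof <- enumerate_isoforms(align_reads(rs, REF), "B", REF)
    prof$proportions
  }
  p1 <- est(d1, 41); p2 <- est(d2, 42)
  delta_ne <- p2["NonEdited"] - p1["NonEdited"]
  delta_b <- p2["B"] - p1["B"]
  expect_equal(unname(delta_ne), -unname(delta_b), tolerance = 1e-9)
  expect_lt(abs(delta_b - (-8)), 4 * 100 * sqrt(2 * 0.2 * 0.8 / 20000))
})
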