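test_that("severity classification follows the MADRS-first rule", {
  expect_equal(as.character(classify_severity("DEP", 18L, NA)), "low")
  expect_equal(as.character(classify_severity("DEP", 35L, NA)), "severe")
  # MADRS takes precedence over a discordant IDS-C30
  expect_equal(as.character(classify_severity("DEP", 20L, 10L)), "moderate")
  # IDS-C30 used only when MADRS is missing
  expect_equal(as.character(classify_severity("SA", NA, 24L)), "moderate")
  expect_equal(as.character(classify_severity("SA", NA, 37L)), "severe")
  # controls always map to none
  expect_equal(as.character(classify_severity("Ctrl", 25L, 30L)), "none")
  expect_error(classify_severity("DEP", NA, NA), "missing")
})

test_that("low-severity exclusion reproduces the analysis-group sizes", {
  bd <- cohort_severity_breakdown()
  rec <- rbind(
    data.frame(group = "Ctrl", MADRS = 0L, IDSC30 = 0L)[rep(1, 99), ],
    records_from_severity_counts(bd$DEP, "DEP"),
    records_from_severity_counts(bd$SA, "SA"))
  kept <- filter_analysis_set(rec)
  tab <- table(kept$group)
  expect_equal(unname(tab[["DEP"]]), 82L)
  expect_equal(unname(tab[["SA"]]), 76L)
  expect_equal(sum(kept$group != "Ctrl"), 158L)  # merged MDD group
  expect_equal(unname(tab[["Ctrl"]]), 99L)       # controls never removed
  excl <- attr(kept, "excluded")
  expect_equal(unname(excl[["DEP"]]), 19L)
  expect_equal(unname(excl[["SA"]]), 8L)

  # a patient rescued by the IDS-C30 arm of the OR
  rec2 <- data.frame(group = "SA", MADRS = 10L, IDSC30 = c(24L, 23L))
  expect_equal(nrow(filter_analysis_set(rec2)), 1)
})

test_that("Wilcoxon rank-sum test matches exact enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p.value, 2 / choose(6, 3))  # = 0.1 by enumeration
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_warning(w0 <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2)),
                 "constant")
  expect_equal(w0$p.value, 1)
})

test_that("Wilcoxon type-I error is near nominal under the null", {
  set.seed(101)
  rej <- mean(replicate(1000, {
    wilcoxon_rank_sum(rnorm(20), rnorm(20))$p.value < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("Welch test from summaries agrees with raw-data Welch", {
  s <- welch_t_summary(41, 14.4, 99, 36.3, 12.9, 84)
  expect_equal(round(s$p.value, 2), 0.02)

  # raw data constructed to have exactly those moments
  make <- function(n, m, sd) {
    x <- scale(rnorm(n))[, 1]
    m + sd * x
  }
  set.seed(5)
  x <- make(99, 41, 14.4); y <- make(84, 36.3, 12.9)
  r <- welch_t(x, y)
  expect_equal(r$t, s$t, tolerance = 1e-9)
  expect_equal(r$df, s$df, tolerance = 1e-9)
  expect_equal(r$p.value, s$p.value, tolerance = 1e-9)

  # identical summaries: t = 0, p = 1
  s0 <- welch_t_summary(5, 1, 10, 5, 1, 10)
  expect_equal(s0$t, 0)
  expect_equal(s0$p.value, 1)
  # equal n and sd: Satterthwaite df reduces to 2n - 2
  expect_equal(welch_t_summary(3, 2, 15, 4, 2, 15)$df, 28)
})

test_that("BH adjustment is step-up, monotone and permutation-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)            # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))  # all equal unchanged

  set.seed(2)
  for (i in 1:20) {
    p <- runif(15)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in raw p
    perm <- sample(15)
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("feature correlations behave at the null and the diagonal", {
  set.seed(9)
  noise <- as.data.frame(matrix(rnorm(100 * 5), 100, 5))
  cm <- site_correlation_matrix(noise)
  expect_equal(unname(diag(cm$r)), rep(1, 5))
  expect_true(isSymmetric(cm$r))
  off <- cm$r[upper.tri(cm$r)]
  expect_lt(mean(abs(off)), 0.2)

  noise$V5 <- 1  # zero variance -> reported missing
  cm <- site_correlation_matrix(noise)
  expect_true(all(is.na(cm$r["V5", ])))
})

test_that("simulated cohorts show concerted positive site correlations", {
  co <- simulate_cohort(cohort_config(n_ctrl = 60, n_dep = 0, n_sa = 0,
                                      reads_per_replicate = 3000,
                                      replicates = 5, seed = 13))
  cf <- cohort_features(co)
  cm <- site_correlation_matrix(cf$features,
                                grep("^site_", names(cf$features),
                                     value = TRUE))
  expect_true(all(cm$r[upper.tri(cm$r)] > 0))
})

test_that("percent mean variation follows the definition and its sign", {
  expect_equal(mean_variation(20, 20), 0)
  expect_equal(mean_variation(10, 9), -10)
  expect_equal(mean_variation(20, 18.72), -6.4)
  expect_true(is.na(mean_variation(0, 5)))
  expect_equal(sign(mean_variation(c(2, 2), c(3, 1))), c(1, -1))
})

test_that("qPCR normalisation divides by the housekeeping geometric mean", {
  q <- c(PDE8A = 8, HPRT1 = 2, GAPDH = 2, TBP = 2, PGK1 = 2)
  expect_equal(qpcr_relative_expression(q, "PDE8A"), 4)
  q <- c(PDE8A = 1, HPRT1 = 1, GAPDH = 1, TBP = 1, PGK1 = 1)
  expect_equal(qpcr_relative_expression(q, "PDE8A"), 1)
  q <- c(PDE8A = 2^1.5, HPRT1 = 1, GAPDH = 2, TBP = 4, PGK1 = 8)
  expect_equal(qpcr_relative_expression(q, "PDE8A"), 1)  # geomean = 2^1.5
  q["TBP"] <- 0
  expect_error(qpcr_relative_expression(q, "PDE8A"), "> 0")
})

test_that("differential table adjusts within comparison and flags effects", {
  # one feature, one comparison: adjusted p equals raw p
  set.seed(3)
  feats <- data.frame(group = rep(c("Ctrl", "SA"), each = 20),
                      site_B = c(rnorm(20, 20), rnorm(20, 15)))
  dt <- differential_table(feats, "site_B", "Ctrl vs SA")
  expect_equal(dt$p_w_adj, dt$p_w)
  expect_equal(dt$p_t_adj, dt$p_t)

  # absent group names the comparison
  expect_error(differential_table(feats, "site_B", "DEP vs SA"),
               "DEP vs SA")

  # group effect placed on sites B, C, E only: D and F stay quiet
  ctrl <- default_control_distribution()
  p <- unclass(ctrl)
  p[c("B", "BC", "BE")] <- 0.6 * p[c("B", "BC", "BE")]
  p["NonEdited"] <- 1 - sum(p[names(p) != "NonEdited"])
  sa_dist <- isoform_distribution(p)
  co <- simulate_cohort(cohort_config(
    n_ctrl = 40, n_dep = 0, n_sa = 40, sa_dist = sa_dist,
    reads_per_replicate = 5000, replicates = 5, seed = 19))
  cf <- cohort_features(co)
  dt <- differential_table(cf$features,
                           grep("^site_", names(cf$features), value = TRUE),
                           "Ctrl vs SA")
  sig <- setNames(dt$sig, dt$feature)
  expect_true(all(sig[c("site_B", "site_C", "site_E")]))
  expect_false(any(sig[c("site_D", "site_F")]))
  # direction: decrease in SA for the targeted sites
  expect_true(all(dt$mean_b[dt$feature %in%
                              c("site_B", "site_C", "site_E")] <
                    dt$mean_a[dt$feature %in%
                                c("site_B", "site_C", "site_E")]))
})

test_that("the BH family keeps null rejections near the nominal rate", {
  set.seed(71)
  prop_sig <- replicate(200, {
    feats <- data.frame(group = rep(c("Ctrl", "SA"), each = 30),
                        matrix(rnorm(60 * 8), 60, 8))
    dt <- differential_table(feats, paste0("X", 1:8), "Ctrl vs SA")
    mean(dt$sig)
  })
  expect_lte(mean(prop_sig), 0.06)
})
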