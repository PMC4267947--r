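# Mutation-frequency estimators, event counting, and the rescue statistic.

test_that("effective genomes follow the design and dominance class", {
  expect_equal(effective_genomes(screen_design("f1_clonal_screen", 5128)),
               10256)
  expect_equal(effective_genomes(screen_design("f1_clonal_screen", 5128),
                                 "dominant"), 10256)
  sel <- screen_design("f2_selection", F1 = 2000, F2 = 68000)
  expect_equal(effective_genomes(sel, "recessive"), 34000)
  expect_equal(effective_genomes(sel, "dominant"), 102000)
  expect_error(screen_design("f2_selection", F1 = 2000),
               class = "ws_argument_error")
})

test_that("frequency estimators do the combined and independent arithmetic", {
  e <- estimate_f_combined(4, F1 = 5128, F2 = 8000)
  expect_equal(e$f_hat, 4 / 14256, tolerance = 1e-12)
  expect_equal(e$G, 14256)
  expect_equal(estimate_f_combined(2, 0, 16)$f_hat, 0.25)
  expect_equal(estimate_f_combined(0, 5128, 0)$f_hat, 0)

  expect_equal(estimate_f_independent(2, 10256)$f_hat, 2 / 10256)
  expect_equal(estimate_f_independent(4, 27256)$f_hat, 4 / 27256,
               tolerance = 1e-12)
  expect_equal(estimate_f_independent(0, 10256)$f_hat, 0)

  # the Poisson interval brackets the point estimate and scales with G
  expect_lte(e$ci_low, e$f_hat)
  expect_gte(e$ci_high, e$f_hat)
  e2 <- estimate_f_independent(4, 27256)
  expect_lt(e2$ci_high, estimate_f_independent(4, 10256)$ci_high)

  expect_error(estimate_f_combined(1, 0, 0), class = "ws_argument_error")
  expect_error(estimate_f_independent(1, 0), class = "ws_argument_error")
  expect_error(estimate_f_combined(-1, 10, 10), class = "ws_argument_error")
})

test_that("independent events are counted by signature clustering", {
  # five isolates, two sharing an identical linked-variant signature
  expect_equal(count_independent_events(list(c("v1", "v2"), c("v2", "v1"),
                                             "v3", "v4", c("v5", "v6"))), 4L)
  # three isolates, two sharing
  expect_equal(count_independent_events(list("w1", "w1", "w2")), 2L)
  # all distinct
  expect_equal(count_independent_events(list("a", "b", "c")), 3L)

  # permutation-invariant and idempotent
  set.seed(301)
  sigs <- replicate(12, sample(paste0("v", 1:6), sample(1:3, 1)),
                    simplify = FALSE)
  n0 <- count_independent_events(sigs)
  for (i in 1:5) {
    expect_equal(count_independent_events(sample(sigs)), n0)
  }
  expect_equal(count_independent_events(sigs), n0)

  expect_error(count_independent_events(list()), class = "ws_argument_error")
  expect_error(count_independent_events(list(character(0))),
               class = "ws_argument_error")
})

test_that("transmission rate carries its binomial standard error", {
  tr <- transmission_rate(50, 100)
  expect_equal(tr$t, 0.5)
  expect_equal(tr$se, 0.05)
  tr2 <- transmission_rate(30, 60)
  expect_equal(tr2$t, 0.5)
  expect_equal(tr2$se, sqrt(0.25 / 60), tolerance = 1e-12)
  expect_warning(tr0 <- transmission_rate(0, 100), "boundary")
  expect_equal(tr0$t, 0)
  expect_equal(tr0$se, 0)
  expect_error(transmission_rate(5, 0), class = "ws_argument_error")
})

test_that("the rescue ratio and its delta-method SEM are computed", {
  # equal fractions on both foods: equal odds, r = 1
  for (p in c(0.2, 0.5, 0.8)) {
    a <- rescue_assay(100, round(100 * p), 200, round(200 * p))
    expect_equal(rescue_ratio(a)$r, 1, tolerance = 1e-12)
  }

  # worked case: f = 0.25, t = 0.5 with N = 100 each
  est <- rescue_ratio(rescue_assay(100, 25, 100, 50))
  expect_equal(est$r, 1 / 3, tolerance = 1e-12)
  expect_equal(est$sem_r,
               (1 / 3) * sqrt(1 / (100 * 0.25 * 0.75) + 1 / (100 * 0.25)),
               tolerance = 1e-12)
  expect_equal(est$sem_r, 0.1018, tolerance = 1e-3)

  # reciprocal orientation option
  est_rev <- rescue_ratio(rescue_assay(100, 25, 100, 50),
                          orientation = "transmission_odds")
  expect_equal(est_rev$r, 3, tolerance = 1e-12)

  # boundary counts are refused unless the continuity correction is asked for
  expect_error(rescue_ratio(rescue_assay(100, 0, 100, 50)),
               class = "ws_degenerate_error")
  cc <- rescue_ratio(rescue_assay(100, 0, 100, 50), continuity = TRUE)
  expect_gt(cc$r, 0)
  expect_lt(cc$r, 0.1)
})

test_that("rescue significance is a Pearson chi-squared with Bonferroni", {
  # identical fractions: chi2 = 0, p = 1
  s0 <- rescue_significance(rescue_assay(100, 30, 200, 60))
  expect_equal(s0$chi2, 0, tolerance = 1e-12)
  expect_equal(s0$p_raw, 1)

  # hand-computed Pearson statistic as the independent oracle
  a <- rescue_assay(100, 10, 100, 50)
  o <- matrix(c(10, 90, 50, 50), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi2_hand <- sum((o - e)^2 / e)
  s <- rescue_significance(a)
  expect_equal(s$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(s$chi2, 38.1, tolerance = 1e-3)
  expect_lt(s$p_raw, 1e-9)

  # Bonferroni over m lines
  am <- rescue_assay(60, 20, 60, 30, m = 8)
  sm <- rescue_significance(am)
  expect_equal(sm$p_adjusted, min(1, 8 * sm$p_raw))

  # Yates flag defers to the corrected statistic
  sy <- rescue_significance(a, yates = TRUE)
  expect_lt(sy$chi2, s$chi2)
})

test_that("the delta-method SEM matches the sampling spread of r", {
  set.seed(302)
  cfg <- synthetic_config(rescue = list(t = 0.5, e_n = 0.5, e_t = 0.25,
                                        brood_d = 1000, brood_h = 400))
  reps <- 400L
  r <- numeric(reps)
  sem <- numeric(reps)
  for (i in seq_len(reps)) {
    est <- rescue_ratio(generate_rescue_assay(cfg))
    r[i] <- est$r
    sem[i] <- est$sem_r
  }
  expect_lt(abs(stats::sd(r) / mean(sem) - 1), 0.15)
  # orientation: transgenics escaping less than siblings pushes r below 1
  expect_lt(mean(r), 1)
  expect_equal(mean(r), 0.5, tolerance = 0.05)
})

test_that("rescue assays round-trip through the tidy TSV interface", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("line_id\tfood\tn_transgenic\tn_total",
               "L1\tDA837\t25\t100",
               "L1\tHB101\t50\t100",
               "L2\tDA837\t40\t80",
               "L2\tHB101\t60\t120"), tsv)
  assays <- read_rescue_assays_tsv(tsv)
  expect_named(assays, c("L1", "L2"))
  expect_equal(assays$L1$k_D, 25)
  expect_equal(assays$L2$m, 2)
  expect_equal(rescue_ratio(assays$L1)$r, 1 / 3, tolerance = 1e-12)
  out <- tempfile(fileext = ".tsv")
  est <- write_rescue_estimates_tsv(assays, out)
  expect_equal(nrow(read.delim(out)), 2L)
  expect_equal(est$r[1], 1 / 3, tolerance = 1e-12)
  unlink(c(tsv, out))
})
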