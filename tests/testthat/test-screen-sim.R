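# EMS mutagenesis, the two screen designs, and backcross dilution.

test_that("mutagenized gametes acquire mutations at the modelled rates", {
  set.seed(201)
  gm <- fixture_map()
  genes <- genetic_map(locus("sef-1", "II", 5))
  p0 <- hermaphrodite(gm, list("eat-5" = "ad1402"))

  # f = 0: no gamete carries a suppressor allele
  g0 <- mutagenize_gametes(p0, mutagenesis_model(genes, 0), gm, 2000L)
  expect_true(all(g0$alleles[, "sef-1"] == "+"))
  expect_equal(nrow(g0$events), 0L)

  # per-genome hit rate f
  n <- 20000L
  f <- 5e-3
  g <- mutagenize_gametes(p0, mutagenesis_model(genes, f), gm, n)
  hits <- mean(g$alleles[, "sef-1"] != "+")
  expect_lt(abs(hits - f), prop_tol(f, n))
  expect_equal(nrow(g$events), sum(g$alleles[, "sef-1"] != "+"))
  # every event id is unique (independent events stay distinguishable)
  expect_false(anyDuplicated(g$events$allele_id) > 0)

  # Poisson background burden
  gb <- mutagenize_gametes(p0, mutagenesis_model(genes, 0, background_rate = 3),
                           gm, 10000L)
  expect_lt(abs(nrow(gb$background) / 10000 - 3), 4 * sqrt(3 / 10000))

  expect_error(mutagenesis_model(genes, -0.1), class = "ws_argument_error")
  expect_error(mutagenesis_model(genes, 1.2), class = "ws_argument_error")
})

test_that("F1 carrier and suppressed-F2 frequencies follow 2f and f/2", {
  f <- 5e-4
  # exact: two mutagenized genomes per F1
  expect_equal(expected_f1_carrier_fraction(f), 2 * f - f^2, tolerance = 1e-12)
  # exact composition with the enumerated selfing distribution
  expect_equal(expected_suppressed_f2_fraction(f, "recessive"),
               2 * f * (1 - f) / 4 + f^2, tolerance = 1e-12)
  expect_equal(expected_suppressed_f2_fraction(f, "dominant"),
               2 * f * (1 - f) * 3 / 4 + f^2, tolerance = 1e-12)
  # first-order laws
  expect_equal(expected_f1_carrier_fraction(f) / (2 * f), 1, tolerance = 1e-3)
  expect_equal(expected_suppressed_f2_fraction(f, "recessive") / (f / 2), 1,
               tolerance = 2e-3)
})

test_that("the F1 clonal screen keeps one isolate per line", {
  set.seed(202)
  genes <- genetic_map(locus("sef-1", "II", 5))
  f <- 1e-3
  design <- screen_design("f1_clonal_screen", F1 = 5128)
  res <- run_f1_clonal_screen(design, mutagenesis_model(genes, f))
  expect_equal(nrow(res$lines), 5128L)
  n_sup <- sum(res$lines$suppressed)
  p <- expected_f1_carrier_fraction(f)
  expect_lt(abs(n_sup / 5128 - p), prop_tol(p, 5128))
  # in the clonal screen each isolate is an independent event
  expect_equal(res$genes$n, res$genes$n_i)

  # with certain mutation in two genes, every line still yields one isolate
  genes2 <- genetic_map(locus("sef-1", "II", 5), locus("sef-2", "IV", 20))
  res2 <- run_f1_clonal_screen(screen_design("f1_clonal_screen", F1 = 40),
                               mutagenesis_model(genes2, 1))
  expect_true(all(res2$lines$suppressed))
  expect_equal(sum(res2$genes$n), 40L)

  expect_error(screen_design("f1_clonal_screen", F1 = 0),
               class = "ws_argument_error")
  expect_error(run_f1_clonal_screen(screen_design("f2_selection", 10, 100),
                                    mutagenesis_model(genes, f)),
               class = "ws_argument_error")
})

test_that("the F2 selection tracks the expected suppressed fraction", {
  set.seed(203)
  genes_r <- genetic_map(locus("sef-1", "II", 5))
  f <- 1e-3
  F2 <- 200000L
  des <- screen_design("f2_selection", F1 = F2, F2 = F2)
  res <- run_f2_selection(des, mutagenesis_model(genes_r, f))
  p <- expected_suppressed_f2_fraction(f, "recessive")
  expect_lt(abs(sum(res$genes$n) / F2 - p), prop_tol(p, F2))

  # dominant suppressor: frequency tracks 3f/2
  genes_d <- genetic_map(locus("sef-d", "II", 5, dominance = "dominant"))
  res_d <- run_f2_selection(des, mutagenesis_model(genes_d, f))
  p_d <- expected_suppressed_f2_fraction(f, "dominant")
  expect_lt(abs(sum(res_d$genes$n) / F2 - p_d), prop_tol(p_d, F2))

  # f = 0: nothing comes through
  res0 <- run_f2_selection(des, mutagenesis_model(genes_r, 0))
  expect_equal(sum(res0$genes$n), 0L)

  # recurrent isolates of one F1 mutation collapse in n_i
  expect_true(all(res$genes$n_i <= res$genes$n))
  expect_error(run_f2_selection(screen_design("f1_clonal_screen", 10),
                                mutagenesis_model(genes_r, f)),
               class = "ws_argument_error")
})

test_that("backcross dilution is exactly 4 (autosomal), 2 (X), 1 (linked)", {
  gm <- genetic_map(locus("sef-1", "II", 5), locus("bgA", "IV", 10),
                    locus("bgX", "X", 2), locus("bgL", "II", 5))
  st <- hermaphrodite(gm, list("sef-1" = "m1", "bgA" = "ba",
                               "bgX" = "bx", "bgL" = "bl"))
  d <- backcross_dilution(st, gm, "sef-1", c("bgA", "bgX", "bgL"))
  expect_equal(d$dilution[d$locus == "bgA"], 4, tolerance = 1e-12)
  expect_equal(d$dilution[d$locus == "bgX"], 2, tolerance = 1e-12)
  expect_equal(d$dilution[d$locus == "bgL"], 1, tolerance = 1e-12)

  # partial linkage sits between no dilution and the unlinked factor
  gm2 <- genetic_map(locus("sef-1", "II", 5), locus("bgP", "II", 15))
  st2 <- hermaphrodite(gm2, list("sef-1" = "m1", "bgP" = "bp"))
  dp <- backcross_dilution(st2, gm2, "sef-1", "bgP")$dilution
  expect_gt(dp, 1)
  expect_lt(dp, 4)

  # Monte Carlo pedigrees agree with the analytic post-round frequencies
  set.seed(204)
  mc <- simulate_backcross_round(st, gm, "sef-1", c("bgA", "bgX", "bgL"),
                                 n_pedigrees = 4000L)
  expect_lt(abs(mc$freq_after[["bgA"]] - 0.25), prop_tol(0.25, 4000))
  expect_lt(abs(mc$freq_after[["bgX"]] - 0.5), prop_tol(0.5, 4000))
  expect_equal(mc$freq_after[["bgL"]], 1)
  expect_true(all(mc$selected$sex == "hermaphrodite"))

  nosup <- hermaphrodite(gm, list("bgA" = "ba"))
  expect_error(backcross_dilution(nosup, gm, "sef-1", "bgA"),
               class = "ws_argument_error")
  expect_error(simulate_backcross_round(nosup, gm, "sef-1", "bgA", 10),
               class = "ws_argument_error")
})

test_that("estimators recover the simulated mutation frequency", {
  set.seed(205)
  genes <- genetic_map(locus("sef-1", "II", 5))
  f <- 2e-3
  model <- mutagenesis_model(genes, f)
  d1 <- screen_design("f1_clonal_screen", F1 = 2000)
  d2 <- screen_design("f2_selection", F1 = 20000, F2 = 20000)
  reps <- 60L
  f_hat <- vapply(seq_len(reps), function(i) {
    n <- sum(run_f1_clonal_screen(d1, model)$genes$n) +
      sum(run_f2_selection(d2, model)$genes$n)
    estimate_f_combined(n, F1 = 2000, F2 = 20000)$f_hat
  }, numeric(1))
  se <- stats::sd(f_hat) / sqrt(reps)
  expect_lt(abs(mean(f_hat) - f), 3 * se)
})

test_that("screen results round-trip through TSV and JSON", {
  set.seed(206)
  genes <- genetic_map(locus("sef-1", "II", 5))
  res <- run_f1_clonal_screen(screen_design("f1_clonal_screen", F1 = 500),
                              mutagenesis_model(genes, 5e-3))
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_screen_result(res, tsv, js)
  back <- read_screen_counts(js)
  expect_equal(back$F1, 500)
  expect_equal(back$n$`sef-1`, res$genes$n[1])
  expect_equal(back$n_i$`sef-1`, res$genes$n_i[1])
  lines <- read.delim(tsv)
  expect_equal(nrow(lines), 500L)
  unlink(c(tsv, js))
})
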