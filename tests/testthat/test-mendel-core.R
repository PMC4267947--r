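# Mendelian transmission engine: gametes, crosses, exact enumeration.

test_that("gamete segregation follows binomial expectations", {
  set.seed(101)
  gm <- fixture_map()
  n <- 10000L

  # homozygous parent: every gamete is the shared haplotype
  hom <- hermaphrodite(gm, list("eat-5" = "ad1402"))
  g <- make_gametes(hom, gm, 100L)
  expect_true(all(g$alleles[, "eat-5"] == "ad1402"))
  expect_true(all(g$alleles[, "sef-1"] == "+"))

  # heterozygous autosomal locus transmits either allele with prob 1/2
  het <- hermaphrodite(gm, list("sef-1" = c("m1", "+")))
  g <- make_gametes(het, gm, n)
  expect_lt(abs(mean(g$alleles[, "sef-1"] == "m1") - 0.5),
            prop_tol(0.5, n, 3))

  # a male transmits his X in half of gametes, nullo-X otherwise
  m <- male(gm, list("unc-2" = "e55"))
  g <- make_gametes(m, gm, n)
  expect_lt(abs(mean(g$x_bearing) - 0.5), prop_tol(0.5, n, 3))
  expect_true(all(g$alleles[g$x_bearing, "unc-2"] == "e55"))
  expect_true(all(g$alleles[!g$x_bearing, "unc-2"] == "O"))

  # single-gamete wrapper returns a named vector
  g1 <- make_gamete(het, gm)
  expect_named(g1, gm$name)
})

test_that("crosses combine gametes and assign sex by X inheritance", {
  set.seed(102)
  gm <- fixture_map()
  n <- 4000L
  mo <- hermaphrodite(gm, list("eat-5" = "ad1402"))

  # eat-5; sef/+ male x eat-5 hermaphrodite: half the progeny carry sef
  fa <- male(gm, list("eat-5" = "ad1402", "sef-1" = c("m1", "+")))
  off <- cross(cross_spec(mo, fa, n), gm)
  carry_sef <- grepl("m1", off[["sef-1"]], fixed = TRUE)
  expect_lt(abs(mean(carry_sef) - 0.5), prop_tol(0.5, n))

  # sex ratio of an outcross is 1/2
  expect_lt(abs(mean(off$sex == "male") - 0.5), prop_tol(0.5, n))

  # eat-5; unc-2/O male x eat-5 hermaphrodite: ALL cross hermaphrodites
  # carry unc-2 (paternal X), no male does (maternal X is wild)
  fx <- male(gm, list("eat-5" = "ad1402", "unc-2" = "e55"))
  off <- cross(cross_spec(mo, fx, n), gm)
  herms <- off$sex == "hermaphrodite"
  expect_true(all(grepl("e55", off[["unc-2"]][herms], fixed = TRUE)))
  expect_true(all(off[["unc-2"]][!herms] == "+/O"))

  # selfing a fully homozygous hermaphrodite clones the parent
  off <- cross(cross_spec(mo, NULL, 50L), gm)
  expect_true(all(off$sex == "hermaphrodite"))
  expect_true(all(off[["eat-5"]] == "ad1402/ad1402"))
  expect_true(all(off[["sef-1"]] == "+/+"))

  # argument errors
  expect_error(cross_spec(fa, NULL, 10), class = "ws_argument_error")
  expect_error(cross_spec(mo, mo, 10), class = "ws_argument_error")
  expect_error(cross_spec(mo, NULL, 0), class = "ws_argument_error")
})

test_that("exact enumeration reproduces Mendelian ratios and linkage", {
  gm1 <- genetic_map(locus("A", "III", 0))
  het <- hermaphrodite(gm1, list(A = c("a", "+")))
  d <- enumerate_offspring_distribution(cross_spec(het), gm1)
  p <- setNames(d$prob, d$A)
  expect_equal(p[["+/a"]], 0.5)
  expect_equal(p[["a/a"]], 0.25)
  expect_equal(p[["+/+"]], 0.25)

  # selfing eat-5; sef/+ : sef homozygote probability 1/4
  gm <- fixture_map()
  h <- hermaphrodite(gm, list("eat-5" = "ad1402", "sef-1" = c("m1", "+")))
  d <- enumerate_offspring_distribution(cross_spec(h), gm)
  expect_equal(sum(d$prob[d[["sef-1"]] == "m1/m1"]), 0.25)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)

  # two linked loci in repulsion, theta = 0.1 test-cross: recombinant
  # classes appear with conditional probability 0.1
  gm2 <- genetic_map(locus("A", "III", 0), locus("B", "III", 10))
  rep_het <- hermaphrodite(gm2, list(A = c("a", "+"), B = c("+", "b")))
  tester <- male(gm2, list(A = "a", B = "b"))
  d <- enumerate_offspring_distribution(cross_spec(rep_het, tester), gm2)
  rec <- (d$A == "a/a" & d$B == "b/b") | (d$A == "+/a" & d$B == "+/b")
  expect_equal(sum(d$prob[rec]), 0.1, tolerance = 1e-12)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)

  # haldane option shrinks theta below d/100
  d_h <- enumerate_offspring_distribution(cross_spec(rep_het, tester), gm2,
                                          map_function = "haldane")
  expect_equal(sum(d_h$prob[(d_h$A == "a/a" & d_h$B == "b/b") |
                            (d_h$A == "+/a" & d_h$B == "+/b")]),
               (1 - exp(-0.2)) / 2, tolerance = 1e-12)

  # capacity guard
  big <- genetic_map(do.call(rbind, lapply(1:13, function(i)
    locus(paste0("L", i), "II", i))))
  manyhet <- hermaphrodite(big, setNames(
    lapply(1:13, function(i) c("m", "+")), paste0("L", 1:13)))
  expect_error(enumerate_offspring_distribution(cross_spec(manyhet), big),
               class = "ws_capacity_error")
})

test_that("stochastic crosses match exact enumeration class by class", {
  set.seed(103)
  gm <- genetic_map(locus("A", "I", 0), locus("B", "I", 20),
                    locus("C", "IV", 0))
  mo <- hermaphrodite(gm, list(A = c("a", "+"), B = c("+", "b")))
  fa <- male(gm, list(C = c("c", "+")))
  spec <- cross_spec(mo, fa, 6000L)
  exact <- enumerate_offspring_distribution(spec, gm)
  off <- cross(spec, gm)
  n <- nrow(off)
  counts <- genotype_class_counts(off, gm)
  key <- function(d) paste(d$A, d$B, d$C, d$sex)
  obs <- setNames(counts$count, key(counts))
  for (i in seq_len(nrow(exact))) {
    p <- exact$prob[i]
    o <- obs[[key(exact[i, ])]]
    if (is.null(o) || is.na(o)) o <- 0L
    expect_lt(abs(o / n - p), prop_tol(p, n), label = sprintf(
      "class %s: |%.4f - %.4f|", key(exact[i, ]), o / n, p))
  }
  expect_equal(sum(counts$count), n)
})

test_that("offspring distribution is invariant to haplotype relabeling", {
  gm <- genetic_map(locus("A", "I", 0), locus("B", "I", 10),
                    locus("X1", "X", 2))
  a <- hermaphrodite(gm, list(A = c("a", "+"), B = c("+", "b"),
                              X1 = c("x", "+")))
  b <- hermaphrodite(gm, list(A = c("+", "a"), B = c("b", "+"),
                              X1 = c("+", "x")))
  fa <- male(gm, list(A = c("a", "+")))
  canon <- function(d) d[do.call(order, as.list(d)), , drop = FALSE]
  da <- canon(enumerate_offspring_distribution(cross_spec(a, fa), gm))
  db <- canon(enumerate_offspring_distribution(cross_spec(b, fa), gm))
  rownames(da) <- rownames(db) <- NULL
  expect_equal(da, db, tolerance = 1e-12)
})

test_that("phenotype frequencies image the offspring distribution", {
  # dominance test: suppressor male x marked eat-5 hermaphrodite, escape
  # among cross hermaphrodites vs the control cross without the suppressor
  gm <- genetic_map(locus("dpy-5", "I", 0), locus("eat-5", "I", 1),
                    locus("sef-d", "II", 5, dominance = "dominant"),
                    locus("sef-r", "III", 5))
  mo <- hermaphrodite(gm, list("dpy-5" = "d1", "eat-5" = "ad1402"))
  rule_d <- suppressor_rule("sef-d", "dominant", eat5 = "eat-5")
  rule_r <- suppressor_rule("sef-r", "recessive", eat5 = "eat-5")
  esc <- function(ph) {
    h <- ph[ph$sex == "hermaphrodite" & grepl("escape", ph$phenotype), ]
    sum(h$probability)
  }
  ctrl <- male(gm, list("eat-5" = "ad1402"))
  p_ctrl_d <- esc(phenotype_frequencies(cross_spec(mo, ctrl), rule_d, gm))

  # dominant suppressor: half the cross progeny escape; control none
  fa_d <- male(gm, list("eat-5" = "ad1402", "sef-d" = c("m", "+")))
  p_d <- esc(phenotype_frequencies(cross_spec(mo, fa_d), rule_d, gm))
  expect_equal(p_d, 0.5)
  expect_gt(p_d, p_ctrl_d)

  # recessive suppressor in the same cross: no escape, equal to control
  fa_r <- male(gm, list("eat-5" = "ad1402", "sef-r" = c("m", "+")))
  p_r <- esc(phenotype_frequencies(cross_spec(mo, fa_r), rule_r, gm))
  p_ctrl_r <- esc(phenotype_frequencies(cross_spec(mo, ctrl), rule_r, gm))
  expect_equal(p_r, p_ctrl_r)

  # a rule mapping everything to one label gives probability 1, and
  # probabilities sum to 1 within each sex class
  allrule <- phenotype_rule(escapes_arrest = function(geno) TRUE)
  ph <- phenotype_frequencies(cross_spec(mo, fa_d), allrule, gm)
  expect_true(all(ph$phenotype == "escape"))
  for (s in unique(ph$sex)) {
    expect_equal(sum(ph$probability[ph$sex == s]), 1, tolerance = 1e-12)
  }

  # visible markers are scored on homozygotes
  mrule <- phenotype_rule(visible_markers = list(
    Dpy = function(g) is_mutant_hom(g, "dpy-5")))
  ph <- phenotype_frequencies(cross_spec(mo), mrule, gm)
  expect_equal(sum(ph$probability[ph$phenotype == "Dpy"]), 1)
})
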