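# Backcross dilution of background mutations.
#
# One round follows the bench scheme: (1) suppressor strain hermaphrodite
# crossed with a clean eat-5 male; (2) a suppressor-carrying male progeny
# crossed with a clean eat-5 hermaphrodite; suppressor-carrying
# hermaphrodite progeny of the second cross are kept, and the strain is
# re-homozygosed for the suppressor by selfing. Dilution of a background
# mutation is the factor by which its expected allele frequency drops in
# the re-homozygosed strain, i.e. measured on suppressor-bearing gametes of
# the selected hermaphrodite. Unlinked autosomal mutations dilute fourfold
# per round, X-linked ones twofold (the male's X passes intact to all his
# hermaphrodite progeny), and a mutation completely linked in cis to the
# suppressor is not diluted at all.

row_carries <- function(al, locus_name) {
  a <- al[, locus_name]
  a != WT & a != NULLO
}

ordered_to_individual <- function(ord, i, map, sex) {
  g <- cbind(mat = ord$mat[i, ], pat = ord$pat[i, ])
  rownames(g) <- colnames(ord$mat)
  class(g) <- c("genotype", class(g))
  individual(sex, g, map, generation = "BC")
}

## P(gamete carries each of `targets` | gamete carries `suppressor`),
## from the exact gamete distribution of one individual.
gamete_cond_freq <- function(ind, map, suppressor, targets, map_function) {
  tg <- enumerate_gametes(ind, map, map_function)
  sel <- row_carries(tg$alleles, suppressor)
  if (!any(sel)) ws_stop("individual transmits no suppressor-bearing gametes")
  w <- tg$prob[sel] / sum(tg$prob[sel])
  vapply(targets, function(b) {
    sum(w * row_carries(tg$alleles[sel, , drop = FALSE], b))
  }, numeric(1))
}

#' Analytic backcross dilution
#'
#' Computes, by exact enumeration through the cross engine, the expected
#' allele-frequency dilution of tagged background mutations over one
#' two-cross backcross round with selection for the suppressor (see the
#' scheme described above). The reported factor is
#' `frequency before / expected frequency after`, where frequency is taken
#' in the suppressor-homozygous strain recovered after the round.
#'
#' @param strain A hermaphrodite [individual()] carrying the suppressor and
#'   the background mutations.
#' @param map The [genetic_map()] (must contain suppressor and background
#'   loci).
#' @param suppressor Name of the suppressor locus.
#' @param background Character vector of background-mutation locus names.
#' @param map_function Passed to [recombination_fraction()].
#' @return A data frame with one row per background mutation: `locus`,
#'   `freq_before`, `freq_after`, `dilution`.
#' @examples
#' gm <- genetic_map(locus("sef-1", "II", 5), locus("bg1", "IV", 10))
#' st <- hermaphrodite(gm, list("sef-1" = "m1", "bg1" = "b1"))
#' backcross_dilution(st, gm, "sef-1", "bg1")   # dilution 4
#' @export
backcross_dilution <- function(strain, map, suppressor, background,
                               map_function = c("morgan", "haldane")) {
  map_function <- match.arg(map_function)
  validate_individual(strain, map)
  if (strain$sex != "hermaphrodite") ws_stop("`strain` must be a hermaphrodite")
  if (!carries(strain$genotype, suppressor)) {
    ws_stop("`strain` must carry the suppressor mutation")
  }
  before <- gamete_cond_freq(strain, map, suppressor, background, map_function)

  clean_male <- male(map, list())
  clean_herm <- hermaphrodite(map, list())
  o1 <- enumerate_offspring_ordered(cross_spec(strain, clean_male), map,
                                    map_function)
  sel1 <- o1$sex == "male" &
    (row_carries(o1$mat, suppressor) | row_carries(o1$pat, suppressor))
  if (!any(sel1)) ws_stop("no suppressor-carrying male progeny in cross 1")
  w1 <- o1$prob[sel1] / sum(o1$prob[sel1])
  idx1 <- which(sel1)

  after <- stats::setNames(numeric(length(background)), background)
  for (k in seq_along(idx1)) {
    bc_male <- ordered_to_individual(o1, idx1[k], map, "male")
    o2 <- enumerate_offspring_ordered(cross_spec(clean_herm, bc_male), map,
                                      map_function)
    sel2 <- o2$sex == "hermaphrodite" &
      (row_carries(o2$mat, suppressor) | row_carries(o2$pat, suppressor))
    if (!any(sel2)) next
    w2 <- o2$prob[sel2] / sum(o2$prob[sel2])
    idx2 <- which(sel2)
    contrib <- stats::setNames(numeric(length(background)), background)
    for (j in seq_along(idx2)) {
      herm <- ordered_to_individual(o2, idx2[j], map, "hermaphrodite")
      contrib <- contrib +
        w2[j] * gamete_cond_freq(herm, map, suppressor, background, map_function)
    }
    after <- after + w1[k] * contrib
  }
  data.frame(locus = background, freq_before = as.numeric(before),
             freq_after = as.numeric(after),
             dilution = as.numeric(before) / as.numeric(after),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Vectorized rejection sampling: redraw gamete rows failing `ok_fun` until
## all pass. mat/pat are n x L matrices of the (per-row) parents.
rejection_gametes <- function(mat, pat, sex, map, map_function, ok_fun,
                              max_tries = 10000L) {
  g <- pop_gametes(mat, pat, sex, map, map_function)
  bad <- which(!ok_fun(g$alleles, g$x_bearing))
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > max_tries) {
      ws_stop("rejection sampling failed: conditioning event too rare",
              class = "ws_capacity_error")
    }
    sub <- pop_gametes(mat[bad, , drop = FALSE], pat[bad, , drop = FALSE],
                       rep_len(sex, nrow(mat))[bad], map, map_function)
    g$alleles[bad, ] <- sub$alleles
    g$x_bearing[bad] <- sub$x_bearing
    bad <- bad[!ok_fun(sub$alleles, sub$x_bearing)]
  }
  g
}

#' Monte Carlo backcross round
#'
#' Simulates `n_pedigrees` independent single rounds of the two-cross
#' backcross scheme and, for each pedigree, samples one suppressor-bearing
#' gamete of the selected hermaphrodite to score carriage of each
#' background mutation. The mean carriage rate estimates the post-round
#' allele frequency that [backcross_dilution()] computes exactly.
#'
#' @inheritParams backcross_dilution
#' @param n_pedigrees Number of independent pedigrees.
#' @return A list: `selected` (a [cross()]-style population of the selected
#'   hermaphrodites), `carrier` (pedigrees x background logical matrix),
#'   `freq_before`, `freq_after` (empirical), and `dilution` (estimated).
#' @export
simulate_backcross_round <- function(strain, map, suppressor, background,
                                     n_pedigrees = 1000L,
                                     map_function = c("morgan", "haldane")) {
  map_function <- match.arg(map_function)
  validate_individual(strain, map)
  if (strain$sex != "hermaphrodite") ws_stop("`strain` must be a hermaphrodite")
  if (!carries(strain$genotype, suppressor)) {
    ws_stop("`strain` must carry the suppressor mutation")
  }
  n <- as.integer(n_pedigrees)
  wild_row <- function() matrix(WT, nrow = n, ncol = nrow(map),
                                dimnames = list(NULL, map$name))
  xcols <- which(map$chromosome == "X")

  ## cross 1: strain hermaphrodite x clean male; keep a suppressor-bearing
  ## male offspring per pedigree (the maternal gamete must carry the
  ## suppressor; sex is independent of it, so males come for free)
  st <- rep_genotype(strain, n)
  g1 <- rejection_gametes(st$mat, st$pat, strain$sex, map, map_function,
                          function(al, xb) row_carries(al, suppressor))
  male_mat <- g1$alleles
  male_pat <- wild_row()
  if (length(xcols)) male_pat[, xcols] <- NULLO

  ## cross 2: that male x clean hermaphrodite; keep a suppressor-carrying
  ## hermaphrodite (paternal gamete X-bearing and suppressor-bearing)
  g2 <- rejection_gametes(male_mat, male_pat, "male", map, map_function,
                          function(al, xb) xb & row_carries(al, suppressor))
  herm_mat <- wild_row()
  herm_pat <- g2$alleles
  selected <- build_population(herm_mat, herm_pat, "hermaphrodite", map, "BC1")

  ## re-homozygose: one suppressor-bearing gamete of each selected hermaphrodite
  g3 <- rejection_gametes(herm_mat, herm_pat, "hermaphrodite", map, map_function,
                          function(al, xb) row_carries(al, suppressor))
  carrier <- vapply(background, function(b) row_carries(g3$alleles, b),
                    logical(n))
  if (n == 1L) carrier <- matrix(carrier, nrow = 1L,
                                 dimnames = list(NULL, background))
  before <- gamete_cond_freq(strain, map, suppressor, background, map_function)
  after <- colMeans(carrier)
  list(selected = selected, carrier = carrier,
       freq_before = before, freq_after = after,
       dilution = before / after)
}
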