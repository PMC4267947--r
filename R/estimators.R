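# Mutation-frequency estimators, effective genomes, independent-event
# counting, and the transgene rescue statistic.

#' Effective genomes screened
#'
#' The number of mutagenized haploid genomes a design effectively
#' interrogates. For the F1 clonal screen it is `2 * F1` (each F1 carries
#' two mutagenized genomes and carriers of either dominance class are
#' recognized). For the F2 selection it is reconstructed from the expected
#' suppressed-F2 fraction: a recessive suppressor appears at frequency
#' `f/2` among F2s, so `G = F2/2`; a dominant one at `3f/2`, so
#' `G = 3*F2/2`.
#'
#' @param design A [screen_design()].
#' @param dominance Dominance class of the suppressor sought.
#' @return Effective genome count (nonnegative real).
#' @examples
#' effective_genomes(screen_design("f1_clonal_screen", F1 = 5128))  # 10256
#' @export
effective_genomes <- function(design, dominance = c("recessive", "dominant")) {
  stopifnot(inherits(design, "screen_design"))
  dominance <- match.arg(dominance)
  if (design$kind == "f1_clonal_screen") {
    2 * design$F1
  } else {
    if (is.null(design$F2)) ws_stop("F2 selection design lacks an F2 count")
    if (dominance == "recessive") design$F2 / 2 else 3 * design$F2 / 2
  }
}

frequency_estimate <- function(f_hat, G, n_events, conf_level = 0.95) {
  ci <- stats::poisson.test(n_events, conf.level = conf_level)$conf.int / G
  structure(list(f_hat = f_hat, G = G, n_events = n_events,
                 ci_low = ci[1L], ci_high = ci[2L],
                 conf_level = conf_level),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("mutation frequency f = %.4g per mutagenized haploid genome\n",
              x$f_hat))
  cat(sprintf("  events = %d over G = %.6g effective genomes; %g%% CI [%.4g, %.4g]\n",
              x$n_events, x$G, 100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Estimate the per-gene mutation frequency from combined screen yields
#'
#' Combines the F1 clonal screen and the F2 selection: with `n` total
#' suppressor isolates of one gene across both designs,
#' `f = n / (2*F1 + F2/2)` (recessive suppressors). The 95% interval is an
#' exact Poisson interval for the isolate count at exposure
#' `G = 2*F1 + F2/2`, reflecting that isolates are rare events over many
#' genomes; the source reports the point estimate only.
#'
#' @param n Total suppressor isolates of the gene (both designs).
#' @param F1 Number of F1s in the clonal screen (0 if not run).
#' @param F2 Number of viable F2s in the selection (0 if not run).
#' @param conf_level Confidence level of the Poisson interval.
#' @return A `"frequency_estimate"`: `f_hat`, `G`, `ci_low`, `ci_high`.
#' @examples
#' estimate_f_combined(4, F1 = 5128, F2 = 8000)  # 4/14256
#' @export
estimate_f_combined <- function(n, F1, F2, conf_level = 0.95) {
  if (any(c(n, F1, F2) < 0) || n != round(n)) {
    ws_stop("`n`, `F1`, `F2` must be nonnegative; `n` an integer")
  }
  G <- 2 * F1 + F2 / 2
  if (G <= 0) ws_stop("2*F1 + F2/2 must be positive")
  frequency_estimate(n / G, G, as.integer(n), conf_level)
}

#' Estimate the mutation frequency from independent events
#'
#' The sharper estimator available when alleles have been sequenced and
#' recurrent isolations of one mutational event can be collapsed:
#' `f = n_i / G` with `n_i` the number of independent events (see
#' [count_independent_events()]) and `G` the effective genomes screened.
#'
#' @param n_i Number of independent mutational events (nonnegative integer).
#' @param G Effective genomes screened (positive).
#' @inheritParams estimate_f_combined
#' @return A `"frequency_estimate"`.
#' @examples
#' estimate_f_independent(2, G = 10256)
#' @export
estimate_f_independent <- function(n_i, G, conf_level = 0.95) {
  if (n_i < 0 || n_i != round(n_i)) ws_stop("`n_i` must be a nonnegative integer")
  if (!is.numeric(G) || G <= 0) ws_stop("`G` must be positive")
  frequency_estimate(n_i / G, G, as.integer(n_i), conf_level)
}

#' Count independent mutational events among sequenced alleles
#'
#' EMS produces mostly GC-to-AT transitions; isolates descending from one
#' mutational event share the identical set of closely linked EMS-induced
#' variants. Isolates are clustered by identical variant signature and the
#' number of clusters is the number of independent events. Deterministic,
#' permutation-invariant and idempotent.
#'
#' @param signatures A list, one element per isolate: a non-empty character
#'   vector of linked-variant identifiers. Order within a signature is
#'   irrelevant.
#' @return Integer: number of distinct signatures.
#' @examples
#' # five isolates, two sharing one event: four independent events
#' count_independent_events(list(c("v1", "v2"), c("v1", "v2"),
#'                               "v3", "v4", c("v5", "v6")))
#' @export
count_independent_events <- function(signatures) {
  if (!is.list(signatures) || length(signatures) == 0L) {
    ws_stop("`signatures` must be a non-empty list")
  }
  keys <- vapply(signatures, function(s) {
    s <- as.character(s)
    if (length(s) == 0L || any(!nzchar(s))) {
      ws_stop("each isolate needs a non-empty variant signature")
    }
    paste(sort(unique(s)), collapse = "\r")
  }, character(1))
  length(unique(keys))
}

## ---- transgene rescue ------------------------------------------------------

#' Transgene rescue assay counts
#'
#' The four counts of a rescue-from-arrest assay with an extrachromosomal
#' array: worms reaching L4 on restrictive food (DA837; `N_D` total, `k_D`
#' transgenic) and on permissive food (HB101; `N_H` total, `k_H`
#' transgenic), plus the number of lines tested in the experiment for
#' Bonferroni correction.
#'
#' @param N_D,k_D Total and transgenic counts on DA837.
#' @param N_H,k_H Total and transgenic counts on HB101.
#' @param m Number of lines tested alongside (for Bonferroni; `>= 1`).
#' @return A list of class `"rescue_assay"`.
#' @export
rescue_assay <- function(N_D, k_D, N_H, k_H, m = 1L) {
  v <- c(N_D = N_D, k_D = k_D, N_H = N_H, k_H = k_H, m = m)
  if (any(v < 0) || any(v != round(v))) {
    ws_stop("all rescue counts must be nonnegative integers")
  }
  if (k_D > N_D || k_H > N_H) ws_stop("transgenic counts cannot exceed totals")
  if (m < 1) ws_stop("`m` must be >= 1")
  structure(as.list(v), class = "rescue_assay")
}

#' Transgene transmission rate
#'
#' Fraction of progeny on permissive food that inherit the array,
#' `t = k_H / N_H`, with its binomial standard error
#' `sqrt(t (1 - t) / N_H)`. Boundary estimates (0 or 1) give SE 0 and a
#' warning, since they carry no information about sampling error.
#'
#' @param k_H Transgenic worms counted on HB101.
#' @param N_H Total worms counted on HB101 (`> 0`).
#' @return A list with `t` and `se`.
#' @examples
#' transmission_rate(50, 100)
#' @export
transmission_rate <- function(k_H, N_H) {
  if (N_H <= 0 || N_H != round(N_H)) ws_stop("`N_H` must be a positive integer")
  if (k_H < 0 || k_H > N_H || k_H != round(k_H)) {
    ws_stop("`k_H` must be an integer in [0, N_H]")
  }
  t <- k_H / N_H
  if (t == 0 || t == 1) {
    warning("boundary transmission estimate: standard error degenerate at 0")
  }
  list(t = t, se = sqrt(t * (1 - t) / N_H))
}

#' Relative escape from arrest (rescue ratio)
#'
#' The rescue statistic compares the fraction transgenic among escapers on
#' restrictive food, `f = k_D / N_D`, with the transmission rate
#' `t = k_H / N_H` measured on permissive food, as an odds ratio:
#' \deqn{r = \frac{f (1 - t)}{t (1 - f)}}
#' Values near 1 mean transgenic worms escape arrest as well as their
#' non-transgenic siblings; values much less than 1 mean the transgene
#' restores arrest (rescue of the suppressor mutation). The standard error
#' is the delta-method propagation of the two binomial fractions on the log
#' scale:
#' \deqn{SEM_r = r \sqrt{\frac{1}{N_D f (1-f)} + \frac{1}{N_H t (1-t)}}}
#' `orientation = "transmission_odds"` returns the reciprocal, for readers
#' who prefer escape of transgenics relative to non-transgenics inverted.
#'
#' @param assay A [rescue_assay()].
#' @param orientation `"transgenic_odds"` (default; r < 1 indicates rescue)
#'   or `"transmission_odds"` (the reciprocal).
#' @param continuity Haldane--Anscombe correction: add 0.5 to all four cells
#'   of the implied 2x2 tables. By default boundary fractions are refused
#'   instead.
#' @return A list of class `"rescue_estimate"`: `t`, `f` (fraction
#'   transgenic on restrictive food), `r`, `sem_r`.
#' @examples
#' a <- rescue_assay(N_D = 100, k_D = 25, N_H = 100, k_H = 50)
#' rescue_ratio(a)  # r = 1/3
#' @export
rescue_ratio <- function(assay,
                         orientation = c("transgenic_odds", "transmission_odds"),
                         continuity = FALSE) {
  stopifnot(inherits(assay, "rescue_assay"))
  orientation <- match.arg(orientation)
  N_D <- assay$N_D; k_D <- assay$k_D; N_H <- assay$N_H; k_H <- assay$k_H
  if (continuity) {
    k_D <- k_D + 0.5; N_D <- N_D + 1
    k_H <- k_H + 0.5; N_H <- N_H + 1
  } else if (k_D == 0 || k_D == assay$N_D || k_H == 0 || k_H == assay$N_H) {
    ws_stop(paste("boundary fraction (0 or 1): the odds ratio is degenerate;",
                  "rerun with `continuity = TRUE` for a Haldane-Anscombe",
                  "corrected estimate"),
            class = "ws_degenerate_error")
  }
  f <- k_D / N_D
  t <- k_H / N_H
  r <- (f * (1 - t)) / (t * (1 - f))
  if (orientation == "transmission_odds") r <- 1 / r
  sem_r <- r * sqrt(1 / (N_D * f * (1 - f)) + 1 / (N_H * t * (1 - t)))
  structure(list(t = t, f = f, r = r, sem_r = sem_r,
                 orientation = orientation),
            class = "rescue_estimate")
}

#' @export
print.rescue_estimate <- function(x, ...) {
  cat(sprintf("relative escape from arrest r = %.4g (SEM %.4g)\n", x$r, x$sem_r))
  cat(sprintf("  fraction transgenic on DA837 f = %.4g; transmission rate t = %.4g\n",
              x$f, x$t))
  invisible(x)
}

#' Chi-squared test of a rescue assay
#'
#' Pearson chi-squared test of independence (1 df, no Yates correction by
#' default) on the 2x2 table food x transgenic status, with Bonferroni
#' correction over the `m` lines tested: `p_adjusted = min(1, m * p_raw)`.
#'
#' @inheritParams rescue_ratio
#' @param yates Apply the Yates continuity correction.
#' @return A list with `chi2`, `df`, `p_raw`, `p_adjusted`, `m`.
#' @examples
#' rescue_significance(rescue_assay(100, 10, 100, 50))
#' @export
rescue_significance <- function(assay, yates = FALSE) {
  stopifnot(inherits(assay, "rescue_assay"))
  tab <- matrix(c(assay$k_D, assay$N_D - assay$k_D,
                  assay$k_H, assay$N_H - assay$k_H),
                nrow = 2L, byrow = TRUE,
                dimnames = list(food = c("DA837", "HB101"),
                                status = c("transgenic", "non-transgenic")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    ws_stop("all margins of the 2x2 table must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_raw = ht$p.value,
       p_adjusted = min(1, assay$m * ht$p.value), m = assay$m)
}

#' Analyse a rescue assay end to end
#'
#' Convenience wrapper combining [transmission_rate()], [rescue_ratio()]
#' and [rescue_significance()].
#'
#' @inheritParams rescue_ratio
#' @inheritParams rescue_significance
#' @return A list of class `"rescue_estimate"` with the ratio fields plus
#'   `chi2`, `p_raw`, `p_adjusted`.
#' @export
analyse_rescue <- function(assay,
                           orientation = c("transgenic_odds", "transmission_odds"),
                           continuity = FALSE, yates = FALSE) {
  est <- rescue_ratio(assay, orientation, continuity)
  sig <- rescue_significance(assay, yates)
  est$chi2 <- sig$chi2
  est$p_raw <- sig$p_raw
  est$p_adjusted <- sig$p_adjusted
  est$m <- sig$m
  est
}

#' Read rescue assays from TSV / write estimates as TSV
#'
#' The input format is tidy: columns `line_id`, `food` (`"DA837"` or
#' `"HB101"`), `n_transgenic`, `n_total`, one row per line x food.
#'
#' @param path Input TSV path.
#' @param m Number of lines for Bonferroni (defaults to the number of lines
#'   in the file).
#' @return `read_rescue_assays_tsv()`: a named list of [rescue_assay()]s.
#' @export
read_rescue_assays_tsv <- function(path, m = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "food", "n_transgenic", "n_total")
  if (!all(need %in% names(d))) {
    ws_stop(sprintf("rescue TSV needs columns %s", paste(need, collapse = ", ")),
            class = "ws_structural_error")
  }
  ids <- unique(d$line_id)
  if (is.null(m)) m <- length(ids)
  out <- lapply(ids, function(id) {
    dd <- d[d$line_id == id, ]
    da <- dd[dd$food == "DA837", ]
    hb <- dd[dd$food == "HB101", ]
    if (nrow(da) != 1L || nrow(hb) != 1L) {
      ws_stop(sprintf("line %s needs exactly one DA837 and one HB101 row", id),
              class = "ws_structural_error")
    }
    rescue_assay(da$n_total, da$n_transgenic, hb$n_total, hb$n_transgenic, m)
  })
  stats::setNames(out, ids)
}

#' @rdname read_rescue_assays_tsv
#' @param assays Named list of [rescue_assay()]s.
#' @param ... Passed to [analyse_rescue()].
#' @return `write_rescue_estimates_tsv()`: the estimates data frame,
#'   invisibly (also written to `path`).
#' @export
write_rescue_estimates_tsv <- function(assays, path, ...) {
  rows <- lapply(names(assays), function(id) {
    e <- analyse_rescue(assays[[id]], ...)
    data.frame(line_id = id, t = e$t, f = e$f, r = e$r, sem_r = e$sem_r,
               chi2 = e$chi2, p_raw = e$p_raw, p_adjusted = e$p_adjusted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
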