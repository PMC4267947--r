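# Two-point mapping from marker-thrower counts.
#
# Cross design: a suppressor male is mated to a multiply marked strain
# (one visible recessive marker per chromosome); the resulting F1 males,
# heterozygous for every marker and carrying the suppressor in repulsion
# to the same-chromosome marker, are mated to clean hermaphrodites. Lines
# that received the suppressor from their father (informative lines) are
# scored for which markers they "throw" (segregate as visible homozygotes)
# among self progeny. An unlinked marker is thrown by half the informative
# lines; a marker in repulsion at recombination fraction theta only by the
# fraction theta that received a recombinant paternal gamete.

#' Expected marker-thrower fraction among informative lines
#'
#' Computed by exact enumeration of the F1 male's gametes through the
#' cross engine (not hard-coded): the probability that a paternal gamete
#' carries the marker, conditional on carrying the focal mutation and on
#' producing a hermaphrodite line (X-bearing). For an autosomal marker on
#' another chromosome this is 1/2; for a marker in repulsion on the focal
#' chromosome it is theta; for an X-linked marker with an autosomal focal
#' mutation it is 1 (every hermaphrodite line receives the paternal X), so
#' such markers are uninformative.
#'
#' @param marker,focal Loci from [locus()] (names and chromosomes used).
#' @param theta Recombination fraction in `[0, 0.5]` between marker and
#'   focal mutation when they share a chromosome (ignored otherwise).
#' @param map_function Passed to [recombination_fraction()].
#' @return Probability that an informative line throws the marker.
#' @examples
#' expected_thrower_fraction(locus("rol-6", "II"), locus("dod-6", "III"), 0.5)
#' expected_thrower_fraction(locus("vab-7", "III"), locus("dod-6", "III"), 0.2)
#' @export
expected_thrower_fraction <- function(marker, focal, theta = 0.5,
                                      map_function = c("morgan", "haldane")) {
  map_function <- match.arg(map_function)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 0.5) {
    ws_stop("`theta` must lie in [0, 0.5]")
  }
  if (marker$name == focal$name) ws_stop("marker and focal locus must differ")
  ## place the pair so that the inter-locus distance reproduces `theta`
  marker <- locus(marker$name, marker$chromosome, position = 0)
  d <- if (map_function == "morgan") 100 * theta
       else if (theta < 0.5) -50 * log(1 - 2 * theta) else Inf
  if (!is.finite(d)) d <- 1e6   # theta = 0.5 under Haldane: effectively free
  focal <- locus(focal$name, focal$chromosome,
                 position = if (marker$chromosome == focal$chromosome) d else 0)
  gm <- genetic_map(marker, focal)
  ## F1 male: marker (maternal, from the marked strain) in repulsion to the
  ## focal mutation (paternal, from the suppressor father)
  al <- list()
  al[[marker$name]] <- c("mk", WT)
  al[[focal$name]] <- c(WT, "fc")
  if (focal$chromosome == "X") al[[focal$name]] <- "fc"
  if (marker$chromosome == "X") al[[marker$name]] <- "mk"
  if (marker$chromosome == "X" && focal$chromosome == "X") {
    ws_stop("marker and focal mutation cannot both be X-linked in a male",
            class = "ws_structural_error")
  }
  f1 <- male(gm, al)
  tg <- enumerate_gametes(f1, gm, map_function)
  informative <- tg$x_bearing & row_carries(tg$alleles, focal$name)
  if (!any(informative)) ws_stop("no informative gametes in this configuration")
  sum(tg$prob[informative & row_carries(tg$alleles, marker$name)]) /
    sum(tg$prob[informative])
}

#' Marker-thrower counts from a mapping cross
#'
#' @param total_lines Lines set up from the second cross.
#' @param uninformative_lines Lines discarded before scoring (e.g. throwing
#'   the marker linked to the selection background and thus likely
#'   heterozygous for it rather than the suppressor).
#' @param arrested_lines Lines whose progeny all arrested (did not receive
#'   the suppressor).
#' @param informative_lines Suppressor-bearing lines scored for markers.
#' @param throwers Named integer vector: per marker, how many informative
#'   lines threw it.
#' @return A list of class `"mapping_counts"`.
#' @examples
#' mapping_counts(92, 51, 25, 16,
#'                c("rol-6" = 9, "vab-7" = 0, "unc-31" = 11, "dpy-11" = 9))
#' @export
mapping_counts <- function(total_lines, uninformative_lines, arrested_lines,
                           informative_lines, throwers) {
  v <- c(total_lines, uninformative_lines, arrested_lines, informative_lines)
  if (any(v < 0) || any(v != round(v))) {
    ws_stop("line counts must be nonnegative integers")
  }
  if (uninformative_lines + arrested_lines + informative_lines != total_lines) {
    ws_stop("uninformative + arrested + informative must equal total lines",
            class = "ws_structural_error")
  }
  if (is.null(names(throwers)) || any(throwers < 0) ||
      any(throwers > informative_lines)) {
    ws_stop("`throwers` must be a named vector with counts in [0, informative]")
  }
  structure(list(total_lines = as.integer(total_lines),
                 uninformative_lines = as.integer(uninformative_lines),
                 arrested_lines = as.integer(arrested_lines),
                 informative_lines = as.integer(informative_lines),
                 throwers = throwers),
            class = "mapping_counts")
}

#' Upper confidence bound on the recombination fraction
#'
#' One-sided Clopper--Pearson upper limit for the per-line
#' marker-carrying probability, from `recombinants` throwers among
#' `informative` lines; in centimorgans via the linear small-distance
#' convention `cM = 100 * theta`. For zero recombinants the bound has the
#' closed form `1 - (1 - confidence)^(1/informative)`.
#'
#' @param recombinants Thrower (recombinant) count.
#' @param informative Informative line count (`> 0`).
#' @param confidence One-sided confidence level (default 0.95).
#' @return A list with `theta_upper` (capped at 0.5, the cap flagged by
#'   `capped`) and `cM` (from the uncapped bound).
#' @examples
#' recomb_upper_bound(0, 16)   # about 17.1 cM
#' @export
recomb_upper_bound <- function(recombinants, informative, confidence = 0.95) {
  if (informative <= 0 || informative != round(informative) ||
      recombinants < 0 || recombinants > informative ||
      recombinants != round(recombinants)) {
    ws_stop("need 0 <= recombinants <= informative, informative > 0")
  }
  if (confidence <= 0 || confidence >= 1) {
    ws_stop("`confidence` must lie in (0, 1)")
  }
  theta_u <- stats::qbeta(confidence, recombinants + 1,
                          informative - recombinants)
  list(theta_upper = min(theta_u, 0.5), cM = 100 * theta_u,
       capped = theta_u > 0.5, confidence = confidence)
}

#' Linkage calls and chromosome assignment from thrower counts
#'
#' Each marker's thrower count is tested against its unlinked expectation
#' (1/2 by default) with a two-sided exact binomial test, Bonferroni
#' corrected across the markers tested. Markers significantly below
#' expectation are called `linked` (with a [recomb_upper_bound()] attached);
#' significantly above, `inconclusive`; otherwise `unlinked`. Markers whose
#' unlinked expectation is 1 (an X marker mapped against an autosomal
#' mutation) are `uninformative` and excluded from testing.
#'
#' The assigned chromosome is that of the marker with the strongest
#' depression below expectation (lowest thrower fraction, ties broken by
#' p-value); the significance call of that marker qualifies the assignment.
#' Requiring formal significance before assigning would discard the best
#' supported chromosome exactly in the small-cross regime where mapping
#' panels of ~16 lines operate.
#'
#' @param counts A [mapping_counts()].
#' @param map A [genetic_map()] containing the markers (for chromosomes).
#' @param alpha Familywise significance level.
#' @param expected Named numeric vector of per-marker unlinked expectations;
#'   defaults to 1/2 everywhere (use [expected_thrower_fraction()] for
#'   non-standard configurations).
#' @param confidence Confidence for the recombination bound of linked
#'   markers.
#' @return A list of class `"mapping_result"`: `per_marker` (data frame
#'   with fraction, p-values, call, theta/cM bound), `chromosome`,
#'   `assignment_marker`, `assignment_call`.
#' @examples
#' gm <- genetic_map(locus("rol-6", "II"), locus("vab-7", "III"),
#'                   locus("unc-31", "IV"), locus("dpy-11", "V"))
#' cts <- mapping_counts(92, 51, 25, 16,
#'   c("rol-6" = 9, "vab-7" = 0, "unc-31" = 11, "dpy-11" = 9))
#' linkage_calls(cts, gm)
#' @export
linkage_calls <- function(counts, map, alpha = 0.05, expected = NULL,
                          confidence = 0.95) {
  stopifnot(inherits(counts, "mapping_counts"))
  if (counts$informative_lines == 0L) {
    ws_stop("no informative lines to test")
  }
  markers <- names(counts$throwers)
  if (!all(markers %in% map$name)) {
    ws_stop("all markers must be loci of `map`", class = "ws_structural_error")
  }
  if (is.null(expected)) expected <- stats::setNames(rep(0.5, length(markers)),
                                                     markers)
  n <- counts$informative_lines
  res <- lapply(markers, function(mk) {
    k <- counts$throwers[[mk]]
    e <- expected[[mk]]
    if (e >= 1) {
      return(data.frame(marker = mk,
                        chromosome = map[mk, "chromosome"],
                        throwers = k, informative = n, fraction = k / n,
                        expected = e, p_raw = NA_real_, p_adj = NA_real_,
                        call = "uninformative",
                        theta_upper = NA_real_, cM_upper = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- stats::binom.test(k, n, p = e)$p.value
    data.frame(marker = mk, chromosome = map[mk, "chromosome"],
               throwers = k, informative = n, fraction = k / n,
               expected = e, p_raw = p, p_adj = NA_real_, call = NA_character_,
               theta_upper = NA_real_, cM_upper = NA_real_,
               stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, res)
  tested <- !is.na(pm$p_raw)
  pm$p_adj[tested] <- pmin(1, pm$p_raw[tested] * sum(tested))
  pm$call[tested] <- ifelse(pm$p_adj[tested] < alpha,
                            ifelse(pm$fraction[tested] < pm$expected[tested],
                                   "linked", "inconclusive"),
                            "unlinked")
  for (i in which(pm$call == "linked")) {
    b <- recomb_upper_bound(pm$throwers[i], pm$informative[i], confidence)
    pm$theta_upper[i] <- b$theta_upper
    pm$cM_upper[i] <- b$cM
  }
  below <- which(tested & pm$fraction < pm$expected)
  if (length(below)) {
    best <- below[order(pm$fraction[below], pm$p_raw[below])][1L]
    chrom <- pm$chromosome[best]
    amk <- pm$marker[best]
    acall <- pm$call[best]
  } else {
    chrom <- NA_character_; amk <- NA_character_; acall <- "none"
  }
  structure(list(per_marker = pm, chromosome = chrom,
                 assignment_marker = amk, assignment_call = acall,
                 alpha = alpha),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> assigned chromosome: %s (marker %s, %s)\n",
              x$chromosome, x$assignment_marker, x$assignment_call))
  print(x$per_marker, row.names = FALSE, digits = 4)
  invisible(x)
}

#' X-linkage from backcross carrier fractions
#'
#' In the backcross scheme the second cross distinguishes an autosomal from
#' an X-linked suppressor: an autosomal suppressor is carried by half the
#' cross hermaphrodites, an X-linked one (transmitted on the male's single
#' X) by all of them. The autosomal model is tested one-sided (an excess of
#' carriers is evidence against it); the X-linked all-carrier model is
#' rejected exactly by any non-carrier. The surviving model is returned, or
#' `"inconclusive"` when both or neither survive.
#'
#' @param carrier_fraction Observed carrier fraction among `n` cross
#'   hermaphrodites.
#' @param n Number of cross hermaphrodites scored (`> 0`).
#' @param alpha Significance level for the autosomal test.
#' @return `"autosomal"`, `"X-linked"` or `"inconclusive"`, with the test
#'   detail in attribute `"tests"`.
#' @examples
#' xlinkage_from_backcross(16/16, 16)  # X-linked
#' xlinkage_from_backcross(8/16, 16)   # autosomal
#' xlinkage_from_backcross(12/16, 16)  # inconclusive
#' @export
xlinkage_from_backcross <- function(carrier_fraction, n, alpha = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n)) {
    ws_stop("`n` must be a positive integer")
  }
  if (carrier_fraction < 0 || carrier_fraction > 1) {
    ws_stop("`carrier_fraction` must lie in [0, 1]")
  }
  k <- round(carrier_fraction * n)
  p_auto <- stats::binom.test(k, n, p = 0.5, alternative = "greater")$p.value
  auto_ok <- p_auto >= alpha
  x_ok <- k == n
  call <- if (auto_ok && !x_ok) "autosomal"
          else if (!auto_ok && x_ok) "X-linked"
          else "inconclusive"
  structure(call, tests = list(p_autosomal = p_auto,
                               x_model_rejected = !x_ok,
                               carriers = k, n = n, alpha = alpha))
}

#' Simulate a multiply-marked mapping cross
#'
#' Simulates the informative lines of the standard mapping cross: the F1
#' male is heterozygous for one visible marker per chromosome (maternal,
#' from the marked strain) and carries the focal mutation in repulsion on
#' its own chromosome (paternal). Paternal gametes are drawn from the cross
#' engine; hermaphrodite (X-bearing) gametes carrying the focal mutation
#' found informative lines, and a line throws a marker iff its paternal
#' gamete carried it.
#'
#' @param markers A [genetic_map()] of marker loci, at most one per
#'   chromosome.
#' @param focal A [locus()]: the mutation being mapped (autosomal).
#' @param n_informative Number of informative lines to collect.
#' @param map_function Passed to [recombination_fraction()].
#' @return A [mapping_counts()] (total = informative; the uninformative and
#'   arrested line classes are not simulated).
#' @export
simulate_mapping_cross <- function(markers, focal, n_informative = 16L,
                                   map_function = c("morgan", "haldane")) {
  map_function <- match.arg(map_function)
  stopifnot(inherits(markers, "genetic_map"))
  if (anyDuplicated(markers$chromosome)) {
    ws_stop("at most one marker per chromosome")
  }
  if (focal$chromosome == "X") {
    ws_stop("the simulated design maps autosomal mutations")
  }
  gm <- add_loci(markers, focal)
  al <- lapply(stats::setNames(markers$name, markers$name), function(mk) {
    if (markers$chromosome[markers$name == mk] == "X") "mk" else c("mk", WT)
  })
  al[[focal$name]] <- c(WT, "fc")
  f1 <- male(gm, al)
  collect <- 0L
  throwers <- stats::setNames(integer(nrow(markers)), markers$name)
  while (collect < n_informative) {
    draw <- max(50L, 4L * (n_informative - collect))
    g <- make_gametes(f1, gm, draw, map_function)
    keep <- g$x_bearing & row_carries(g$alleles, focal$name)
    if (!any(keep)) next
    kal <- g$alleles[keep, , drop = FALSE]
    take <- min(nrow(kal), n_informative - collect)
    kal <- kal[seq_len(take), , drop = FALSE]
    for (mk in markers$name) {
      throwers[[mk]] <- throwers[[mk]] + sum(row_carries(kal, mk))
    }
    collect <- collect + take
  }
  mapping_counts(n_informative, 0L, 0L, n_informative, throwers)
}

#' Write a mapping result to disk
#'
#' JSON with the assignment and per-marker table, plus an optional
#' human-readable TSV of the per-marker table.
#'
#' @param result A `"mapping_result"`.
#' @param json_path,tsv_path Output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_mapping_result <- function(result, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(result, "mapping_result"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(chromosome = result$chromosome,
           assignment_marker = result$assignment_marker,
           assignment_call = result$assignment_call,
           alpha = result$alpha,
           per_marker = result$per_marker),
      json_path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(result$per_marker, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}
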