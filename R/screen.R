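# EMS mutagenesis and the two screen designs: mass F2 selection and the
# F1 clonal (plate-per-F1) screen.

## Event-id source local to one simulation run: ids are unique within the
## run and deterministic under a fixed RNG seed. The prefix separates runs
## that might be combined downstream (c = clonal, s = selection, g = gamete).
event_counter <- function(prefix) {
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  function(gene, k) {
    ids <- env$i + seq_len(k)
    env$i <- env$i + k
    sprintf("%s:%s%d", gene, prefix, ids)
  }
}

#' Mutagenesis model
#'
#' Describes EMS mutagenesis of a haploid genome: each suppressor gene in
#' `genes` is hit at most once per transmitted genome, with probability `f`
#' (Bernoulli rather than Poisson -- at the relevant frequencies,
#' f of order 1e-3 or less, the difference is negligible and single-hit
#' bookkeeping keeps alleles identifiable). Independently, a
#' Poisson(`background_rate`) number of neutral background mutations lands
#' at uniform map positions; these matter for backcross-dilution studies.
#'
#' @param genes A [genetic_map()] of suppressor genes (chromosome and
#'   dominance are used).
#' @param f Per-gene mutation probability per mutagenized haploid genome;
#'   scalar or one value per gene, each in `[0, 1]`.
#' @param background_rate Expected neutral background mutations per haploid
#'   genome (`>= 0`).
#' @return A list of class `"mutagenesis_model"`.
#' @examples
#' genes <- genetic_map(locus("sef-1", "II", 5))
#' mutagenesis_model(genes, f = 5e-4)
#' @export
mutagenesis_model <- function(genes, f, background_rate = 0) {
  stopifnot(inherits(genes, "genetic_map"))
  f <- rep_len(as.numeric(f), nrow(genes))
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    ws_stop("`f` must lie in [0, 1]")
  }
  if (!is.numeric(background_rate) || length(background_rate) != 1L ||
      !is.finite(background_rate) || background_rate < 0) {
    ws_stop("`background_rate` must be a nonnegative number")
  }
  structure(list(genes = genes, f = stats::setNames(f, genes$name),
                 background_rate = background_rate),
            class = "mutagenesis_model")
}

#' Draw mutagenized gametes
#'
#' Draws `n` gametes from `parent` and lets each transmitted haploid genome
#' independently acquire suppressor mutations (at most one per gene, with
#' probability `f`) and a Poisson number of tagged neutral background
#' mutations at uniform random map positions. Every mutational event gets
#' an allele id unique within the call, so recurrent isolation of one event
#' stays distinguishable from independent events; under a fixed seed the
#' output is fully deterministic.
#'
#' @inheritParams make_gametes
#' @param model A [mutagenesis_model()]; its genes must be loci of `map`.
#' @return As [make_gametes()], plus `events` (data frame `gamete`, `gene`,
#'   `allele_id`) and `background` (data frame `gamete`, `chromosome`,
#'   `position`, `id`).
#' @export
mutagenize_gametes <- function(parent, model, map, n,
                               map_function = c("morgan", "haldane")) {
  stopifnot(inherits(model, "mutagenesis_model"))
  if (!all(model$genes$name %in% map$name)) {
    ws_stop("all suppressor genes must be loci of `map`",
            class = "ws_structural_error")
  }
  g <- make_gametes(parent, map, n, map_function)
  new_ids <- event_counter("g")
  ev <- list()
  for (gene in model$genes$name) {
    hit <- which(stats::runif(n) < model$f[[gene]])
    if (length(hit)) {
      ids <- new_ids(gene, length(hit))
      g$alleles[hit, gene] <- ids
      ev[[gene]] <- data.frame(gamete = hit, gene = gene, allele_id = ids,
                               stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(gamete = integer(0), gene = character(0),
                            allele_id = character(0))
  rownames(events) <- NULL
  nbg <- stats::rpois(n, model$background_rate)
  tot <- sum(nbg)
  background <- data.frame(
    gamete = rep(seq_len(n), nbg),
    chromosome = sample(CHROMOSOMES, tot, replace = TRUE),
    position = stats::runif(tot, 0, 50),
    id = if (tot) sprintf("bg:g%d", seq_len(tot)) else character(0),
    stringsAsFactors = FALSE)
  c(g, list(events = events, background = background))
}

#' Screen designs
#'
#' `"f1_clonal_screen"`: one gravid F1 per plate, plates scored for
#' segregating suppressed F2s; effective genomes `2 * F1`.
#' `"f2_selection"`: mass selection over `F2` viable F2s plated on
#' restrictive food, descended from a pool of `F1` selfing F1s.
#'
#' @param kind `"f2_selection"` or `"f1_clonal_screen"`.
#' @param F1 Number of F1 individuals (plates for the clonal screen; the
#'   selfing pool for the selection).
#' @param F2 Number of viable F2s plated (selection only).
#' @return A list of class `"screen_design"`.
#' @examples
#' screen_design("f1_clonal_screen", F1 = 5128)
#' screen_design("f2_selection", F1 = 2000, F2 = 68000)
#' @export
screen_design <- function(kind = c("f2_selection", "f1_clonal_screen"),
                          F1, F2 = NULL) {
  kind <- match.arg(kind)
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x < 1 || x != round(x)) {
      ws_stop(sprintf("`%s` must be a positive integer", nm))
    }
    as.integer(x)
  }
  F1 <- chk(F1, "F1")
  if (kind == "f2_selection") {
    if (is.null(F2)) ws_stop("`F2` is required for an F2 selection")
    F2 <- chk(F2, "F2")
  } else if (!is.null(F2)) {
    ws_stop("`F2` applies only to the F2 selection design")
  }
  structure(list(kind = kind, F1 = F1, F2 = F2), class = "screen_design")
}

screen_result <- function(design, lines, genes, n_scored) {
  structure(list(design = design, lines = lines, genes = genes,
                 n_scored = n_scored),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: %d scored, %d isolates\n",
              x$design$kind, x$n_scored, sum(x$genes$n)))
  print(x$genes, row.names = FALSE)
  invisible(x)
}

## Bernoulli(f) hits over two haploid genomes per individual, one gene.
two_genome_hits <- function(n, f, gene, new_ids) {
  h1 <- stats::runif(n) < f
  h2 <- stats::runif(n) < f
  a1 <- rep(WT, n); a2 <- rep(WT, n)
  if (any(h1)) a1[h1] <- new_ids(gene, sum(h1))
  if (any(h2)) a2[h2] <- new_ids(gene, sum(h2))
  cbind(a1, a2)
}

#' Run the F1 clonal screen
#'
#' Simulates the plate-per-F1 screen: each F1 carries two independently
#' mutagenized haploid genomes; a plate is called suppressed iff its F1
#' carries a suppressor allele (a recessive suppressor segregates
#' homozygous F2s on the plate, so carriers of either dominance class are
#' detectable). Only one isolate is kept per F1 line, even when one plate
#' carries mutations in two genes or two hits in one gene.
#'
#' @param design A [screen_design()] of kind `"f1_clonal_screen"`.
#' @param model A [mutagenesis_model()].
#' @param detection Probability that a suppressor-bearing plate is
#'   recognized (default 1: the frequency estimators assume full
#'   detection; lower values support power studies).
#' @return A `"screen_result"`: `lines` (one row per F1: `line_id`,
#'   `suppressed`, `gene`, `allele_id`), `genes` (per gene: isolate count
#'   `n`, independent events `n_i`), `n_scored`, and the design.
#' @examples
#' genes <- genetic_map(locus("sef-1", "II", 5))
#' res <- run_f1_clonal_screen(screen_design("f1_clonal_screen", F1 = 2000),
#'                             mutagenesis_model(genes, f = 1e-3))
#' @export
run_f1_clonal_screen <- function(design, model, detection = 1) {
  stopifnot(inherits(design, "screen_design"), inherits(model, "mutagenesis_model"))
  if (design$kind != "f1_clonal_screen") {
    ws_stop("`design` must have kind 'f1_clonal_screen'")
  }
  n <- design$F1
  genes <- model$genes$name
  new_ids <- event_counter("c")
  al <- lapply(stats::setNames(genes, genes),
               function(g) two_genome_hits(n, model$f[[g]], g, new_ids))
  lines <- data.frame(line_id = seq_len(n), suppressed = FALSE,
                      gene = NA_character_, allele_id = NA_character_,
                      stringsAsFactors = FALSE)
  for (g in genes) {
    carrier <- al[[g]][, 1L] != WT | al[[g]][, 2L] != WT
    take <- carrier & is.na(lines$gene)   # one isolate per line: first gene
    lines$gene[take] <- g
    lines$allele_id[take] <- ifelse(al[[g]][take, 1L] != WT,
                                    al[[g]][take, 1L], al[[g]][take, 2L])
  }
  found <- !is.na(lines$gene) & stats::runif(n) < detection
  lines$suppressed <- found
  lines$gene[!found] <- NA_character_
  lines$allele_id[!found] <- NA_character_
  iso <- lines[lines$suppressed, , drop = FALSE]
  genes_df <- data.frame(
    gene = genes,
    n = vapply(genes, function(g) sum(iso$gene == g), integer(1)),
    n_i = vapply(genes, function(g) length(unique(iso$allele_id[iso$gene == g])),
                 integer(1)),
    stringsAsFactors = FALSE)
  screen_result(design, lines, genes_df, n_scored = n)
}

#' Run the F2 mass selection
#'
#' Simulates mutagenized P0s whose F1 progeny self; `F2` viable F2s are
#' plated on restrictive food and scored. Each F2 draws its parent from the
#' F1 pool; a recessive suppressor is recovered only as a homozygote
#' (expected suppressed fraction `f/2`), a dominant one also as a
#' heterozygote (`3f/2`). Suppressed F2s are the isolates; independent
#' events are tracked through allele ids, so several isolates descending
#' from one F1 mutation count once in `n_i`.
#'
#' @param design A [screen_design()] of kind `"f2_selection"`.
#' @inheritParams run_f1_clonal_screen
#' @param false_positive Probability that a non-suppressed F2 nevertheless
#'   escapes arrest (rare escapers; default 0).
#' @return A `"screen_result"`; `lines` holds one row per isolate.
#' @export
run_f2_selection <- function(design, model, detection = 1, false_positive = 0) {
  stopifnot(inherits(design, "screen_design"), inherits(model, "mutagenesis_model"))
  if (design$kind != "f2_selection") {
    ws_stop("`design` must have kind 'f2_selection'")
  }
  n1 <- design$F1
  n2 <- design$F2
  genes <- model$genes$name
  dom <- stats::setNames(model$genes$dominance, genes)
  parent <- sample.int(n1, n2, replace = TRUE)
  new_ids <- event_counter("s")
  iso_gene <- rep(NA_character_, n2)
  iso_allele <- rep(NA_character_, n2)
  for (g in genes) {
    f1al <- two_genome_hits(n1, model$f[[g]], g, new_ids)
    pick1 <- stats::runif(n2) < 0.5
    pick2 <- stats::runif(n2) < 0.5
    g1 <- ifelse(pick1, f1al[parent, 1L], f1al[parent, 2L])
    g2 <- ifelse(pick2, f1al[parent, 1L], f1al[parent, 2L])
    expressed <- if (dom[[g]] == "dominant") g1 != WT | g2 != WT
                 else g1 != WT & g2 != WT
    take <- expressed & is.na(iso_gene)
    iso_gene[take] <- g
    iso_allele[take] <- ifelse(g1[take] != WT, g1[take], g2[take])
  }
  suppressed <- !is.na(iso_gene) & stats::runif(n2) < detection
  if (false_positive > 0) {
    suppressed <- suppressed | (is.na(iso_gene) & stats::runif(n2) < false_positive)
  }
  keep <- which(suppressed)
  lines <- data.frame(line_id = keep,
                      suppressed = rep(TRUE, length(keep)),
                      gene = iso_gene[keep], allele_id = iso_allele[keep],
                      stringsAsFactors = FALSE)
  genes_df <- data.frame(
    gene = genes,
    n = vapply(genes, function(g) sum(lines$gene == g, na.rm = TRUE), integer(1)),
    n_i = vapply(genes, function(g)
      length(unique(lines$allele_id[!is.na(lines$gene) & lines$gene == g])),
      integer(1)),
    stringsAsFactors = FALSE)
  screen_result(design, lines, genes_df, n_scored = n2)
}

#' Expected screen-level frequencies
#'
#' `expected_f1_carrier_fraction()` is the exact probability that an F1
#' (two mutagenized haploid genomes) carries a suppressor allele of one
#' gene: `1 - (1 - f)^2`, i.e. `2f` to first order.
#' `expected_suppressed_f2_fraction()` composes that with the exact selfing
#' distribution from [enumerate_offspring_distribution()]: the probability
#' that a heterozygous F1's selfed offspring expresses the suppressor (1/4
#' recessive, 3/4 dominant, obtained by enumeration, not hard-coded), giving
#' `f/2` resp. `3f/2` to first order in `f`.
#'
#' @param f Per-gene mutation probability per haploid genome.
#' @param dominance Dominance of the suppressor.
#' @return A probability.
#' @export
expected_f1_carrier_fraction <- function(f) {
  if (any(f < 0) || any(f > 1)) ws_stop("`f` must lie in [0, 1]")
  1 - (1 - f)^2
}

#' @rdname expected_f1_carrier_fraction
#' @export
expected_suppressed_f2_fraction <- function(f, dominance = c("recessive", "dominant")) {
  dominance <- match.arg(dominance)
  if (any(f < 0) || any(f > 1)) ws_stop("`f` must lie in [0, 1]")
  gm <- genetic_map(locus("sup", "II", 0, dominance = dominance))
  het <- hermaphrodite(gm, list(sup = c("m", WT)))
  rule <- suppressor_rule("sup", dominance)
  ph <- phenotype_frequencies(cross_spec(het), rule, gm)
  p_het <- sum(ph$probability[ph$phenotype == "escape"])
  ## a homozygous (or trans-heterozygous) F1 transmits expressing offspring
  ## with probability 1 for either dominance class
  2 * f * (1 - f) * p_het + f^2
}

#' Write a screen result to disk
#'
#' Line-level TSV (`line_id`, `gene`, `allele_id`, `suppressed`) plus a
#' JSON summary `{kind, F1, F2, n, n_i}`.
#'
#' @param res A `"screen_result"`.
#' @param tsv_path,json_path Output paths (`NULL` to skip one of them).
#' @return Invisibly, a list of the paths written.
#' @export
write_screen_result <- function(res, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(res, "screen_result"))
  if (!is.null(tsv_path)) {
    utils::write.table(res$lines[, c("line_id", "gene", "allele_id", "suppressed")],
                       tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summ <- list(kind = res$design$kind, F1 = res$design$F1,
                 F2 = res$design$F2, n_scored = res$n_scored,
                 n = as.list(stats::setNames(res$genes$n, res$genes$gene)),
                 n_i = as.list(stats::setNames(res$genes$n_i, res$genes$gene)))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}

#' Read a screen-count summary
#'
#' @param path JSON written by [write_screen_result()].
#' @return The summary as a list.
#' @export
read_screen_counts <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
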