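# Seeded generators for every input the pipeline consumes: simulated
# screens, transgenic rescue assays, and per-worm pump/growth datasets.
#
# Defaults mirror the study conditions the estimators were built for:
# a clonal screen of 5128 F1s, a selection over tens of thousands of F2s,
# per-gene mutation frequencies of order 5e-4, and an array transmission
# rate of 0.5 (a placeholder: real transmission rates vary per array and
# are measured, not assumed).

#' Synthetic-data configuration
#'
#' Bundles the generator parameters; identical seed and configuration give
#' identical output. Any subset can be overridden; the rest keep defaults.
#'
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param screen Screen parameters: `f`, `F1`, `F2`, `genes` (a
#'   [genetic_map()]), `background_rate`.
#' @param rescue Rescue-assay parameters: transmission rate `t`, escape
#'   probabilities `e_n` (non-transgenic) and `e_t` (transgenic), brood
#'   sizes `brood_d`, `brood_h`.
#' @param pump Pump-rate parameters: named vectors `mean` and `sd` per
#'   genotype plus per-genotype `n`.
#' @param growth Growth parameters: `brood_sizes`, `generation_time` days.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = NULL, screen = list(), rescue = list(),
                             pump = list(), growth = list()) {
  def_genes <- genetic_map(locus("sef-1", "II", 5),
                           locus("sef-2", "IV", 20),
                           locus("sef-x", "X", 10))
  ## keep the gene map out of modifyList: it would recurse into the
  ## data frame column by column instead of replacing it wholesale
  genes <- if (is.null(screen$genes)) def_genes else screen$genes
  stopifnot(inherits(genes, "genetic_map"))
  screen$genes <- NULL
  cfg <- list(
    seed = seed,
    screen = utils::modifyList(
      list(f = 5e-4, F1 = 5128L, F2 = 68000L, pool_F1 = 2000L,
           background_rate = 0),
      screen),
    rescue = utils::modifyList(
      list(t = 0.5, e_n = 0.5, e_t = 0.5, brood_d = 500L, brood_h = 200L),
      rescue),
    pump = utils::modifyList(
      list(mean = c(wt = 10, a = 30, b = 30, ab = 30),
           sd = 3, n = 12L),
      pump),
    growth = utils::modifyList(
      list(brood_sizes = c(wild = 300, mutant = 7), generation_time = 3.5),
      growth))
  cfg$screen$genes <- genes
  probs <- c(cfg$rescue$t, cfg$rescue$e_n, cfg$rescue$e_t)
  if (any(probs < 0) || any(probs > 1)) {
    ws_stop("rescue probabilities must lie in [0, 1]")
  }
  if (any(c(cfg$rescue$brood_d, cfg$rescue$brood_h) < 1)) {
    ws_stop("brood sizes must be positive")
  }
  structure(cfg, class = "synthetic_config")
}

#' Read a synthetic configuration from YAML
#'
#' The YAML mirrors the arguments of [synthetic_config()]; the screen gene
#' set may be given as a list of loci
#' (`{name: ..., chromosome: ..., position: ..., dominance: ...}`).
#'
#' @param path YAML file path.
#' @return A `"synthetic_config"`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$screen$genes)) {
    y$screen$genes <- do.call(genetic_map, lapply(y$screen$genes, function(l) {
      locus(l$name, l$chromosome, l$position %||% 0,
            l$dominance %||% "recessive")
    }))
  }
  synthetic_config(seed = y$seed,
                   screen = y$screen %||% list(),
                   rescue = y$rescue %||% list(),
                   pump = y$pump %||% list(),
                   growth = y$growth %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a transgene rescue assay
#'
#' Simulates one line's counts. On permissive food every worm reaches L4:
#' `k_H ~ Binomial(brood_h, t)` transgenics among `N_H = brood_h`. On
#' restrictive food each brood member is transgenic with probability `t`
#' and escapes arrest with probability `e_t` (transgenic) or `e_n`
#' (non-transgenic); the escapers are counted (`N_D`) and scored for the
#' array (`k_D`). Under this design the fraction transgenic among escapers
#' satisfies `odds(f) = odds(t) * e_t / e_n`, so the statistic recovered by
#' [rescue_ratio()] estimates the escape-probability ratio `e_t / e_n`
#' (1 when transgene and escape are independent).
#'
#' @param config A [synthetic_config()] (its `rescue` block is used).
#' @param seed Optional seed overriding `config$seed`.
#' @return A [rescue_assay()], with the generating parameters and the true
#'   escape odds ratio in attribute `"truth"`.
#' @export
generate_rescue_assay <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  rc <- config$rescue
  with_seed(seed %||% config$seed, {
    N_H <- rc$brood_h
    k_H <- stats::rbinom(1L, N_H, rc$t)
    tg <- stats::rbinom(1L, rc$brood_d, rc$t)
    k_D <- stats::rbinom(1L, tg, rc$e_t)
    esc_n <- stats::rbinom(1L, rc$brood_d - tg, rc$e_n)
    assay <- rescue_assay(N_D = k_D + esc_n, k_D = k_D, N_H = N_H, k_H = k_H)
    attr(assay, "truth") <- list(t = rc$t, e_n = rc$e_n, e_t = rc$e_t,
                                 escape_ratio = rc$e_t / rc$e_n)
    assay
  })
}

#' Generate screen fixtures
#'
#' Runs both screen designs under one mutagenesis model and optionally
#' writes the line-level TSVs and JSON summaries. The true `f` is recorded
#' so parameter-recovery tests can compare the estimate against ground
#' truth.
#'
#' @inheritParams generate_rescue_assay
#' @param dir Output directory (`NULL` to skip writing).
#' @return A list: `clonal` and `selection` screen results, `truth`
#'   (the mutagenesis parameters), and `paths` when files were written.
#' @export
generate_screen_fixture <- function(config = synthetic_config(), dir = NULL,
                                    seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  sc <- config$screen
  with_seed(seed %||% config$seed, {
    model <- mutagenesis_model(sc$genes, sc$f, sc$background_rate)
    clonal <- run_f1_clonal_screen(
      screen_design("f1_clonal_screen", F1 = sc$F1), model)
    selection <- run_f2_selection(
      screen_design("f2_selection", F1 = sc$pool_F1, F2 = sc$F2), model)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      p <- function(...) file.path(dir, paste0(...))
      write_screen_result(clonal, p("clonal_lines.tsv"), p("clonal_summary.json"))
      write_screen_result(selection, p("selection_lines.tsv"),
                          p("selection_summary.json"))
      paths <- c(p("clonal_lines.tsv"), p("clonal_summary.json"),
                 p("selection_lines.tsv"), p("selection_summary.json"))
    }
    list(clonal = clonal, selection = selection,
         truth = list(f = stats::setNames(rep_len(sc$f, nrow(sc$genes)),
                                          sc$genes$name),
                      genes = sc$genes),
         paths = paths)
  })
}

## Truncated-at-zero normal draws via inverse-CDF on the upper tail.
rtruncnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Generate a per-worm pump-rate dataset
#'
#' Draws per-worm terminal-bulb pump rates from a truncated-at-zero normal
#' per genotype, in the two-factor layout used by the epistasis test. The
#' four genotype labels map onto the factor grid as
#' `wt = (+,+), a = (-,+), b = (+,-), ab = (-,-)`.
#'
#' @inheritParams generate_rescue_assay
#' @param path Optional TSV output path.
#' @return A tidy data frame: `worm_id`, `genotype`, `factor_a`,
#'   `factor_b`, `pumps_per_min`.
#' @export
generate_pump_fixture <- function(config = synthetic_config(), path = NULL,
                                  seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  pc <- config$pump
  genos <- names(pc$mean)
  if (is.null(genos) || length(genos) == 0L) {
    ws_stop("pump means must be a named vector of genotype means")
  }
  sds <- rep_len(pc$sd, length(genos))
  ns <- rep_len(pc$n, length(genos))
  if (any(pc$mean < 0) || any(sds <= 0)) {
    ws_stop("pump means must be >= 0 and SDs > 0")
  }
  if (any(ns < 2L)) ws_stop("need n >= 2 worms per genotype")
  fa <- c(wt = "+", a = "-", b = "+", ab = "-")
  fb <- c(wt = "+", a = "+", b = "-", ab = "-")
  with_seed(seed %||% config$seed, {
    rows <- lapply(seq_along(genos), function(i) {
      data.frame(genotype = genos[i],
                 factor_a = unname(fa[genos[i]]),
                 factor_b = unname(fb[genos[i]]),
                 pumps_per_min = rtruncnorm0(ns[i], pc$mean[i], sds[i]),
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d <- cbind(worm_id = seq_len(nrow(d)), d)
    if (!is.null(path)) {
      utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    d
  })
}

#' Generate growth observations
#'
#' Per-strain food-exhaustion times implied by the log-brood-size growth
#' model: exhaustion time is proportional to `1/ln(B)`, scaled so the
#' first (reference) strain exhausts its plate in `reference_days` days,
#' with multiplicative lognormal noise.
#'
#' @inheritParams generate_rescue_assay
#' @param n_per_strain Replicate plates per strain.
#' @param reference_days Exhaustion time of the first strain (days).
#' @param cv Coefficient of variation of the lognormal plate noise.
#' @return A data frame: `strain`, `days_to_exhaustion`, `growth_rate`.
#' @export
generate_growth_fixture <- function(config = synthetic_config(),
                                    n_per_strain = 5L, reference_days = 7,
                                    cv = 0.1, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  B <- config$growth$brood_sizes
  if (any(B <= 1)) ws_stop("brood sizes must be > 1")
  with_seed(seed %||% config$seed, {
    base_days <- reference_days * log(B[1L]) / log(B)
    rows <- lapply(seq_along(B), function(i) {
      noise <- exp(stats::rnorm(n_per_strain, 0, sqrt(log(1 + cv^2))))
      days <- base_days[i] * noise
      data.frame(strain = names(B)[i], days_to_exhaustion = days,
                 growth_rate = growth_rate(days), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
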