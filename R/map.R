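# Genetic maps: loci on the six C. elegans chromosomes, cM positions, and
# conversion of map distance to recombination fraction.

#' @keywords internal
"_PACKAGE"

## Allele conventions used throughout the package:
##  "+"  wild-type allele
##  "O"  the absent X in an X/O male (paternal slot of X-linked loci)
##  any other non-empty string is a mutant allele identifier.
WT <- "+"
NULLO <- "O"

CHROMOSOMES <- c("I", "II", "III", "IV", "V", "X")

ws_stop <- function(msg, class = "ws_argument_error", call. = FALSE) {
  stop(structure(
    class = c(class, "wormscreen_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

#' Define a locus
#'
#' A locus is a named position on one of the six *C. elegans* chromosomes
#' (I--V and X), with a map position in centimorgans and, for
#' phenotype-bearing loci, a dominance class.
#'
#' @param name Unique locus name (e.g. `"eat-5"`, `"unc-2"`).
#' @param chromosome One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`, `"X"`.
#' @param position Map position in centimorgans (finite, `>= 0`).
#' @param dominance `"recessive"` or `"dominant"`; only meaningful for
#'   phenotype-bearing loci and ignored for neutral markers.
#' @return A one-row data frame describing the locus.
#' @examples
#' locus("eat-5", "I", 0)
#' locus("dod-6", "III", 10, dominance = "dominant")
#' @export
locus <- function(name, chromosome, position = 0,
                  dominance = c("recessive", "dominant")) {
  dominance <- match.arg(dominance)
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      grepl("/", name, fixed = TRUE)) {
    ws_stop("`name` must be a single non-empty string without '/'")
  }
  if (!chromosome %in% CHROMOSOMES) {
    ws_stop(sprintf("`chromosome` must be one of %s",
                    paste(CHROMOSOMES, collapse = ", ")))
  }
  if (!is.numeric(position) || length(position) != 1L ||
      !is.finite(position) || position < 0) {
    ws_stop("`position` must be a finite nonnegative number (cM)")
  }
  data.frame(name = name, chromosome = chromosome,
             position = as.numeric(position), dominance = dominance,
             stringsAsFactors = FALSE)
}

#' Assemble a genetic map
#'
#' Collects loci into a genetic map, ordered by chromosome and position.
#' Locus names must be unique.
#'
#' @param ... Loci created by [locus()], or data frames with columns
#'   `name`, `chromosome`, `position`, `dominance`.
#' @return A data frame of class `"genetic_map"`, one row per locus.
#' @examples
#' gm <- genetic_map(locus("eat-5", "I"), locus("sef-1", "II", 5))
#' @export
genetic_map <- function(...) {
  parts <- list(...)
  if (length(parts) == 0L) ws_stop("a genetic map needs at least one locus")
  m <- do.call(rbind, parts)
  need <- c("name", "chromosome", "position", "dominance")
  if (!all(need %in% names(m))) {
    ws_stop("loci must have columns name, chromosome, position, dominance",
            class = "ws_structural_error")
  }
  if (anyDuplicated(m$name)) {
    ws_stop("locus names must be unique within a genetic map",
            class = "ws_structural_error")
  }
  m <- m[order(match(m$chromosome, CHROMOSOMES), m$position), , drop = FALSE]
  rownames(m) <- m$name
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Add loci to an existing map
#'
#' @param map A [genetic_map()].
#' @param ... Further loci as in [genetic_map()].
#' @return The extended map.
#' @export
add_loci <- function(map, ...) {
  stopifnot(inherits(map, "genetic_map"))
  do.call(genetic_map, c(list(as.data.frame(map)), list(...)))
}

#' Convert map distance to recombination fraction
#'
#' The default `"morgan"` rule reads small centimorgan distances directly as
#' percent recombination (theta = d/100, capped at 1/2), the convention used
#' when quoting two-point distances like "less than 20 cM". The `"haldane"`
#' option applies Haldane's map function theta = (1 - exp(-2d/100))/2.
#'
#' @param d_cM Distance in centimorgans (nonnegative).
#' @param map_function `"morgan"` (linear, capped at 0.5) or `"haldane"`.
#' @return Recombination fraction(s) in `[0, 0.5]`.
#' @examples
#' recombination_fraction(10)             # 0.1
#' recombination_fraction(10, "haldane")  # 0.0906
#' @export
recombination_fraction <- function(d_cM, map_function = c("morgan", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(!is.finite(d_cM)) || any(d_cM < 0)) {
    ws_stop("map distances must be finite and nonnegative")
  }
  switch(map_function,
         morgan = pmin(d_cM / 100, 0.5),
         haldane = (1 - exp(-2 * d_cM / 100)) / 2)
}

## Recombination fraction across two concatenated intervals: a net switch
## needs an odd number of crossovers, so thetas compose as t1 + t2 - 2 t1 t2.
compose_theta <- function(t1, t2) t1 + t2 - 2 * t1 * t2

## Thetas between consecutive rows of `map` restricted to indices `idx`
## (already in map order). Returns numeric of length length(idx) - 1.
adjacent_thetas <- function(map, idx, map_function) {
  if (length(idx) < 2L) return(numeric(0))
  full <- which(map$chromosome == map$chromosome[idx[1L]])
  ## compose per-adjacent-locus interval thetas across intervening loci so
  ## that exact enumeration and the stochastic chain share one model
  iv <- recombination_fraction(diff(map$position[full]), map_function)
  vapply(seq_len(length(idx) - 1L), function(j) {
    lo <- match(idx[j], full)
    hi <- match(idx[j + 1L], full)
    th <- 0
    for (k in seq(lo, hi - 1L)) th <- compose_theta(th, iv[k])
    th
  }, numeric(1))
}

#' Read a genetic map from YAML or JSON
#'
#' The document is a list of loci, each with `name`, `chromosome` and
#' optional `position` (cM, default 0) and `dominance` (default
#' `"recessive"`). The format is chosen by file extension.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(doc$loci)) doc <- doc$loci
  do.call(genetic_map, lapply(doc, function(l) {
    locus(l$name, l$chromosome,
          if (is.null(l$position)) 0 else l$position,
          if (is.null(l$dominance)) "recessive" else l$dominance)
  }))
}

#' Read a cross specification from YAML or JSON
#'
#' The document has a `mother` block and optionally a `father` block
#' (absent for selfing), each with an `alleles` mapping locus to one or two
#' alleles, plus `offspring_count`.
#'
#' @param path File path.
#' @param map The [genetic_map()] the parents live on.
#' @return A [cross_spec()].
#' @export
read_cross_spec <- function(path, map) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  parent <- function(block, sex) {
    al <- lapply(block$alleles, function(a) unlist(a, use.names = FALSE))
    individual(sex, genotype(map, al), map,
               generation = if (is.null(block$generation)) "P0"
                            else block$generation)
  }
  mother <- parent(doc$mother, "hermaphrodite")
  father <- if (is.null(doc$father)) NULL else parent(doc$father, "male")
  n <- if (is.null(doc$offspring_count)) 100L else doc$offspring_count
  cross_spec(mother, father, n)
}

## Run a seed block with the global RNG restored afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
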