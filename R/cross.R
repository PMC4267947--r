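# Crosses: hermaphrodite selfing and male x hermaphrodite outcrosses.

#' Specify a cross
#'
#' Selfing (the *C. elegans* default) takes a hermaphrodite mother only;
#' an outcross additionally takes a male father. Selfing produces only
#' hermaphrodites; in an outcross, offspring receiving a paternal X are
#' hermaphrodites and nullo-X offspring are males (about half each).
#'
#' @param mother A hermaphrodite [individual()].
#' @param father `NULL` for selfing, or a male [individual()].
#' @param offspring_count Positive integer.
#' @return A list of class `"cross_spec"`.
#' @export
cross_spec <- function(mother, father = NULL, offspring_count = 100L) {
  if (!inherits(mother, "individual") || mother$sex != "hermaphrodite") {
    ws_stop("`mother` must be a hermaphrodite individual")
  }
  if (!is.null(father) &&
      (!inherits(father, "individual") || father$sex != "male")) {
    ws_stop("`father` must be NULL (selfing) or a male individual")
  }
  if (!is.numeric(offspring_count) || length(offspring_count) != 1L ||
      offspring_count < 1 || offspring_count != round(offspring_count)) {
    ws_stop("`offspring_count` must be a positive integer")
  }
  structure(list(mother = mother, father = father,
                 offspring_count = as.integer(offspring_count)),
            class = "cross_spec")
}

#' Simulate a cross
#'
#' Draws `offspring_count` offspring by sampling one maternal and one
#' paternal gamete each (for selfing, two independent gametes from the
#' mother). Sex follows X/O inheritance: selfed broods are all
#' hermaphrodite; outcross offspring are hermaphrodite iff the paternal
#' gamete carried the X.
#'
#' @param spec A [cross_spec()].
#' @param map The [genetic_map()].
#' @param map_function Passed to [recombination_fraction()].
#' @param generation Generation label for the offspring.
#' @return A data frame of class `"population"`: columns `id`, `sex`,
#'   `generation`, then one column per locus holding `"maternal/paternal"`
#'   allele pairs (the paternal slot is `"O"` at X loci of males).
#' @examples
#' gm <- genetic_map(locus("eat-5", "I"), locus("sef-1", "II", 5))
#' mo <- hermaphrodite(gm, list("eat-5" = "ad1402"))
#' fa <- male(gm, list("eat-5" = "ad1402", "sef-1" = c("m1", "+")))
#' off <- cross(cross_spec(mo, fa, 50), gm)
#' table(off$sex)
#' @export
cross <- function(spec, map, map_function = c("morgan", "haldane"),
                  generation = "F1") {
  stopifnot(inherits(spec, "cross_spec"))
  map_function <- match.arg(map_function)
  n <- spec$offspring_count
  validate_individual(spec$mother, map)
  gm <- make_gametes(spec$mother, map, n, map_function)
  if (is.null(spec$father)) {
    gp <- make_gametes(spec$mother, map, n, map_function)
    sex <- rep("hermaphrodite", n)
  } else {
    validate_individual(spec$father, map)
    gp <- make_gametes(spec$father, map, n, map_function)
    sex <- ifelse(gp$x_bearing, "hermaphrodite", "male")
  }
  build_population(gm$alleles, gp$alleles, sex, map, generation)
}

build_population <- function(mat, pat, sex, map, generation) {
  n <- nrow(mat)
  pop <- data.frame(id = seq_len(n), sex = sex,
                    generation = rep_len(generation, n),
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(map))) {
    pop[[map$name[j]]] <- paste(mat[, j], pat[, j], sep = "/")
  }
  attr(pop, "loci") <- map$name
  class(pop) <- c("population", "data.frame")
  pop
}

#' Extract one individual from a population
#'
#' @param pop A [cross()] result.
#' @param i Row index.
#' @param map The [genetic_map()].
#' @return An [individual()].
#' @export
get_individual <- function(pop, i, map) {
  stopifnot(inherits(pop, "population"), i >= 1, i <= nrow(pop))
  al <- strsplit(unlist(pop[i, map$name, drop = TRUE], use.names = FALSE),
                 "/", fixed = TRUE)
  g <- matrix(unlist(al), ncol = 2L, byrow = TRUE,
              dimnames = list(map$name, c("mat", "pat")))
  class(g) <- c("genotype", class(g))
  structure(list(sex = pop$sex[i], genotype = g,
                 generation = pop$generation[i]),
            class = "individual")
}

## Unordered genotype-class keys ("a/b" with a <= b per locus), matching the
## classes of enumerate_offspring_distribution().
population_classes <- function(pop, map) {
  keys <- vapply(map$name, function(nm) {
    parts <- strsplit(pop[[nm]], "/", fixed = TRUE)
    vapply(parts, function(p) paste(sort(p), collapse = "/"), character(1))
  }, character(nrow(pop)))
  if (nrow(pop) == 1L) keys <- matrix(keys, nrow = 1L,
                                      dimnames = list(NULL, map$name))
  data.frame(keys, sex = pop$sex, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Tabulate genotype classes of a simulated population
#'
#' Classes are unordered (`A/a` and `a/A` coincide); the key format matches
#' [enumerate_offspring_distribution()], so empirical frequencies can be
#' compared directly with exact probabilities.
#'
#' @inheritParams get_individual
#' @return A data frame with one column per locus, `sex`, and `count`.
#' @export
genotype_class_counts <- function(pop, map) {
  cl <- population_classes(pop, map)
  agg <- stats::aggregate(list(count = rep(1L, nrow(cl))),
                          by = cl, FUN = sum)
  agg
}

#' Write a population as TSV
#'
#' One row per individual: `id`, `sex`, `generation`, one column per locus.
#'
#' @inheritParams get_individual
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(pop, path) {
  utils::write.table(as.data.frame(pop), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
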