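# Diploid genotypes and individuals with X/O sex determination.
#
# A genotype is a character matrix with one row per map locus and two
# columns, "mat" and "pat": the maternally and paternally derived alleles.
# "+" is wild type; any other string is a mutant allele id. X/O males are
# hemizygous: their single X allele sits in the "mat" slot of X-linked rows
# and the "pat" slot holds "O".

#' Build a genotype
#'
#' @param map A [genetic_map()].
#' @param alleles Named list: for each named locus, either a single allele
#'   (homozygous) or a length-2 vector `c(maternal, paternal)`. Loci not
#'   named are wild type (`"+"`).
#' @return Character matrix (loci x 2) of class `"genotype"`, rows in map
#'   order, columns `mat` and `pat`.
#' @examples
#' gm <- genetic_map(locus("eat-5", "I"), locus("sef-1", "II", 5))
#' genotype(gm, list("eat-5" = "ad1402", "sef-1" = c("m1", "+")))
#' @export
genotype <- function(map, alleles = list()) {
  stopifnot(inherits(map, "genetic_map"))
  g <- matrix(WT, nrow = nrow(map), ncol = 2L,
              dimnames = list(map$name, c("mat", "pat")))
  if (length(alleles)) {
    if (is.null(names(alleles)) || !all(names(alleles) %in% map$name)) {
      ws_stop("allele list names must match loci in the map",
              class = "ws_structural_error")
    }
    for (nm in names(alleles)) {
      a <- as.character(alleles[[nm]])
      if (!length(a) %in% 1:2 || any(!nzchar(a)) ||
          any(grepl("/", a, fixed = TRUE))) {
        ws_stop("alleles must be one or two non-empty strings without '/'",
                class = "ws_structural_error")
      }
      g[nm, ] <- if (length(a) == 1L) c(a, a) else a
    }
  }
  class(g) <- c("genotype", class(g))
  g
}

#' Individuals
#'
#' An individual couples a sex, a genotype and a free-text generation label.
#' `hermaphrodite()` and `male()` are convenience constructors;
#' `individual()` is the general one. For males, X-linked loci are made
#' hemizygous: a single supplied allele is kept in the maternal slot and the
#' paternal slot is set to the absent-X marker `"O"`.
#'
#' @param sex `"hermaphrodite"` or `"male"`.
#' @param geno A [genotype()] (or an allele list passed to `genotype()`).
#' @param map A [genetic_map()].
#' @param generation Free-text generation label (`"P0"`, `"F1"`, ...).
#' @return A list of class `"individual"` with elements `sex`, `genotype`,
#'   `generation`.
#' @examples
#' gm <- genetic_map(locus("eat-5", "I"), locus("unc-2", "X"))
#' male(gm, list("eat-5" = "ad1402", "unc-2" = "e55"))
#' @export
individual <- function(sex = c("hermaphrodite", "male"), geno, map,
                       generation = "P0") {
  sex <- match.arg(sex)
  if (!inherits(geno, "genotype")) geno <- genotype(map, geno)
  if (sex == "male") {
    xrows <- map$chromosome == "X"
    if (any(xrows)) {
      gx <- geno[xrows, , drop = FALSE]
      ## accept either an explicit (allele, "O") pair or a homozygous
      ## shorthand, which we reinterpret as hemizygous
      both <- gx[, "pat"] != NULLO & gx[, "pat"] != gx[, "mat"]
      if (any(both)) {
        ws_stop("males carry a single X-linked allele; give one allele per X locus",
                class = "ws_structural_error")
      }
      geno[xrows, "pat"] <- NULLO
    }
  }
  ind <- structure(list(sex = sex, genotype = geno, generation = generation),
                   class = "individual")
  validate_individual(ind, map)
  ind
}

#' @rdname individual
#' @param alleles Named allele list as in [genotype()].
#' @export
hermaphrodite <- function(map, alleles = list(), generation = "P0") {
  individual("hermaphrodite", genotype(map, alleles), map, generation)
}

#' @rdname individual
#' @export
male <- function(map, alleles = list(), generation = "P0") {
  individual("male", genotype(map, alleles), map, generation)
}

#' Validate an individual against a map
#'
#' Checks the X-dosage invariants: hermaphrodites carry two alleles at every
#' locus, males exactly one X-linked allele (paternal slot `"O"`) and two at
#' every autosomal locus.
#'
#' @inheritParams individual
#' @param ind An [individual()].
#' @return `ind`, invisibly; raises a structural error otherwise.
#' @export
validate_individual <- function(ind, map) {
  g <- ind$genotype
  if (!is.matrix(g) || nrow(g) != nrow(map) ||
      !identical(rownames(g), map$name)) {
    ws_stop("genotype rows must match the map loci",
            class = "ws_structural_error")
  }
  if (any(!nzchar(g))) {
    ws_stop("empty allele strings are not allowed", class = "ws_structural_error")
  }
  xrows <- map$chromosome == "X"
  if (ind$sex == "hermaphrodite") {
    if (any(g == NULLO)) {
      ws_stop("hermaphrodites carry two alleles at every locus ('O' not allowed)",
              class = "ws_structural_error")
    }
  } else {
    if (any(g[!xrows, ] == NULLO)) {
      ws_stop("autosomal loci cannot carry the absent-X marker",
              class = "ws_structural_error")
    }
    if (any(xrows) && (any(g[xrows, "pat"] != NULLO) ||
                       any(g[xrows, "mat"] == NULLO))) {
      ws_stop("males are hemizygous: X alleles in the maternal slot, 'O' in the paternal",
              class = "ws_structural_error")
    }
  }
  invisible(ind)
}

## ---- genotype predicates ---------------------------------------------------

#' Genotype predicates
#'
#' Small total predicates over genotypes, used to build phenotype rules.
#' `carries()` is true if any allele slot holds a mutant allele;
#' `is_mutant_hom()` if every present slot (ignoring the absent X `"O"`)
#' is mutant, so a hemizygous mutant male counts as homozygous;
#' `expresses()` applies a dominance class: a recessive allele expresses
#' only when homozygous/hemizygous, a dominant one whenever carried.
#'
#' @param geno A [genotype()] matrix.
#' @param locus_name Locus name (row of the genotype).
#' @param dominance `"recessive"` or `"dominant"`.
#' @return Logical scalar.
#' @export
carries <- function(geno, locus_name) {
  a <- geno[locus_name, ]
  any(a != WT & a != NULLO)
}

#' @rdname carries
#' @export
is_mutant_hom <- function(geno, locus_name) {
  a <- geno[locus_name, ]
  a <- a[a != NULLO]
  length(a) > 0L && all(a != WT)
}

#' @rdname carries
#' @export
expresses <- function(geno, locus_name, dominance = c("recessive", "dominant")) {
  dominance <- match.arg(dominance)
  if (dominance == "dominant") carries(geno, locus_name)
  else is_mutant_hom(geno, locus_name)
}

## ---- phenotype rules -------------------------------------------------------

#' Phenotype rules
#'
#' A phenotype rule maps genotypes to labels. `escapes_arrest` is a
#' predicate deciding whether an animal escapes L1 arrest on restrictive
#' food; `visible_markers` is a named list of predicates for visible marker
#' phenotypes (Bli, Rol, Unc, Dpy, ...). All predicates must be total over
#' valid genotypes.
#'
#' `suppressor_rule()` builds the standard rule for an *eat-5* suppression
#' assay: an animal escapes arrest iff it carries a wild-type *eat-5* allele,
#' or is *eat-5* homozygous mutant and expresses the suppressor according to
#' its dominance.
#'
#' @param escapes_arrest `NULL` or a predicate `function(geno)`.
#' @param visible_markers Named list of predicates `function(geno)`.
#' @return A list of class `"phenotype_rule"`.
#' @examples
#' gm <- genetic_map(locus("eat-5", "I"), locus("sef-1", "II", 5))
#' rule <- suppressor_rule("sef-1", "recessive", eat5 = "eat-5")
#' @export
phenotype_rule <- function(escapes_arrest = NULL, visible_markers = list()) {
  if (!is.null(escapes_arrest) && !is.function(escapes_arrest)) {
    ws_stop("`escapes_arrest` must be NULL or a function of the genotype")
  }
  if (length(visible_markers) &&
      (is.null(names(visible_markers)) ||
       !all(vapply(visible_markers, is.function, logical(1))))) {
    ws_stop("`visible_markers` must be a named list of predicate functions")
  }
  structure(list(escapes_arrest = escapes_arrest,
                 visible_markers = visible_markers),
            class = "phenotype_rule")
}

#' @rdname phenotype_rule
#' @param suppressor Name of the suppressor locus.
#' @param dominance Dominance of the suppressor.
#' @param eat5 Name of the food-sensitive locus (`NULL` if the genotype is
#'   uniformly mutant for it and it is not tracked on the map).
#' @export
suppressor_rule <- function(suppressor, dominance = c("recessive", "dominant"),
                            eat5 = NULL) {
  dominance <- match.arg(dominance)
  force(suppressor); force(eat5)
  phenotype_rule(escapes_arrest = function(geno) {
    if (!is.null(eat5) && !is_mutant_hom(geno, eat5)) return(TRUE)
    expresses(geno, suppressor, dominance)
  })
}

#' Classify one genotype under a phenotype rule
#'
#' @param rule A [phenotype_rule()].
#' @param geno A [genotype()] matrix.
#' @return A single label: the arrest class (if the rule has one) followed
#'   by the names of visible markers expressed, e.g. `"escape Rol"`;
#'   `"(none)"` if the rule assigns nothing.
#' @export
classify_phenotype <- function(rule, geno) {
  stopifnot(inherits(rule, "phenotype_rule"))
  parts <- character(0)
  if (!is.null(rule$escapes_arrest)) {
    parts <- if (isTRUE(rule$escapes_arrest(geno))) "escape" else "arrest"
  }
  for (nm in names(rule$visible_markers)) {
    if (isTRUE(rule$visible_markers[[nm]](geno))) parts <- c(parts, nm)
  }
  if (length(parts) == 0L) "(none)" else paste(parts, collapse = " ")
}
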