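# Meiosis: vectorized gamete sampling.
#
# Transmission is modelled per chromosome as a Markov chain over the loci in
# map order: the first locus takes either parental haplotype with
# probability 1/2, and phase switches between adjacent loci with the
# interval's recombination fraction. Exact enumeration marginalizes the same
# chain, so simulation and enumeration share one model. A male's gamete
# carries his X with probability 1/2 and is otherwise nullo-X.

## Workhorse: one gamete from each of n (possibly distinct) parents.
## mat, pat: n x L character matrices in map row order; sex: length-1 or -n.
## Returns list(alleles = n x L matrix, x_bearing = logical n).
pop_gametes <- function(mat, pat, sex, map,
                        map_function = c("morgan", "haldane")) {
  map_function <- match.arg(map_function)
  n <- nrow(mat)
  L <- nrow(map)
  stopifnot(ncol(mat) == L, identical(dim(mat), dim(pat)))
  sex <- rep_len(sex, n)
  out <- matrix(WT, nrow = n, ncol = L, dimnames = list(NULL, map$name))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    th <- adjacent_thetas(map, idx, map_function)
    phase <- stats::rbinom(n, 1L, 0.5)          # 0 = maternal haplotype
    for (j in seq_along(idx)) {
      if (j > 1L) {
        sw <- stats::rbinom(n, 1L, th[j - 1L])
        phase <- (phase + sw) %% 2L
      }
      k <- idx[j]
      out[, k] <- ifelse(phase == 0L, mat[, k], pat[, k])
    }
    if (chr == "X") {
      ## males are hemizygous: their X haplotype lives in `mat`
      m <- sex == "male"
      if (any(m)) out[m, idx] <- mat[m, idx, drop = FALSE]
    }
  }
  xb <- rep(TRUE, n)
  m <- sex == "male"
  if (any(m)) {
    xb[m] <- stats::rbinom(sum(m), 1L, 0.5) == 1L
    xcols <- which(map$chromosome == "X")
    if (length(xcols)) {
      nullo <- m & !xb
      if (any(nullo)) out[nullo, xcols] <- NULLO
    }
  }
  list(alleles = out, x_bearing = xb)
}

## Replicate one individual's genotype into n x L mat/pat matrices.
rep_genotype <- function(ind, n) {
  g <- ind$genotype
  list(mat = matrix(g[, "mat"], nrow = n, ncol = nrow(g), byrow = TRUE,
                    dimnames = list(NULL, rownames(g))),
       pat = matrix(g[, "pat"], nrow = n, ncol = nrow(g), byrow = TRUE,
                    dimnames = list(NULL, rownames(g))))
}

#' Draw gametes from a parent
#'
#' `make_gametes()` draws `n` independent gametes; `make_gamete()` draws
#' one and returns it as a named allele vector. Heterozygous loci transmit
#' either allele with probability 1/2, loci on different chromosomes assort
#' independently, and adjacent loci co-segregate parentally with
#' probability `1 - theta` where theta comes from
#' [recombination_fraction()]. A male's gamete carries his X with
#' probability 1/2 and is otherwise nullo-X (X-linked slots set to `"O"`).
#'
#' @param parent An [individual()].
#' @param map The [genetic_map()] the genotype lives on.
#' @param n Number of gametes.
#' @param map_function Passed to [recombination_fraction()].
#' @return `make_gametes()`: a list with `alleles` (an `n` x loci character
#'   matrix) and `x_bearing` (logical). `make_gamete()`: a named character
#'   vector with attribute `x_bearing`.
#' @examples
#' gm <- genetic_map(locus("eat-5", "I"), locus("sef-1", "II", 5))
#' h <- hermaphrodite(gm, list("sef-1" = c("m1", "+")))
#' g <- make_gametes(h, gm, 10)
#' @export
make_gametes <- function(parent, map, n,
                         map_function = c("morgan", "haldane")) {
  validate_individual(parent, map)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    ws_stop("`n` must be a positive integer")
  }
  gp <- rep_genotype(parent, n)
  pop_gametes(gp$mat, gp$pat, parent$sex, map, map_function)
}

#' @rdname make_gametes
#' @export
make_gamete <- function(parent, map, map_function = c("morgan", "haldane")) {
  g <- make_gametes(parent, map, 1L, map_function)
  structure(g$alleles[1L, ], x_bearing = g$x_bearing[1L])
}
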