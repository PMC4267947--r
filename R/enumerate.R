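# Exact offspring distributions.
#
# Gamete enumeration marginalizes the same per-chromosome Markov chain used
# by make_gametes(): the phase pattern over heterozygous loci has
# probability 1/2 * prod over adjacent heterozygous pairs of the composed
# switch probability across the intervening intervals. This keeps the exact
# distribution and the stochastic sampler provably consistent.

MAX_SEGREGATING <- 12L

## Heterozygous (segregating) loci of an individual: autosomal mat != pat,
## plus X loci with mat != pat for hermaphrodites. A male's hemizygous X is
## not a heterozygous pair (its segregation rides on X vs nullo-X).
het_loci <- function(ind, map) {
  g <- ind$genotype
  het <- g[, "mat"] != g[, "pat"]
  if (ind$sex == "male") het[map$chromosome == "X"] <- FALSE
  which(het)
}

## Exact gamete distribution of one parent.
## Returns list(alleles = R x L matrix, x_bearing = logical R, prob).
enumerate_gametes <- function(parent, map,
                              map_function = c("morgan", "haldane")) {
  map_function <- match.arg(map_function)
  validate_individual(parent, map)
  g <- parent$genotype
  is_male <- parent$sex == "male"
  hets <- het_loci(parent, map)
  if (length(hets) > MAX_SEGREGATING) {
    ws_stop(sprintf("cannot enumerate: %d segregating loci (max %d)",
                    length(hets), MAX_SEGREGATING),
            class = "ws_capacity_error")
  }

  chrom_block <- function(idx) {
    cols <- map$name[idx]
    ch <- intersect(hets, idx)
    base <- g[idx, "mat"]
    if (length(ch) == 0L) {
      return(list(al = matrix(base, nrow = 1L,
                              dimnames = list(NULL, cols)),
                  prob = 1))
    }
    th <- adjacent_thetas(map, ch, map_function)
    k <- length(ch)
    cfg <- as.matrix(expand.grid(rep(list(0:1), k)))
    prob <- rep(0.5, nrow(cfg))
    if (k > 1L) {
      for (j in 2:k) {
        prob <- prob * ifelse(cfg[, j] != cfg[, j - 1L],
                              th[j - 1L], 1 - th[j - 1L])
      }
    }
    al <- matrix(rep(base, each = nrow(cfg)), nrow = nrow(cfg),
                 dimnames = list(NULL, cols))
    for (j in seq_len(k)) {
      nm <- map$name[ch[j]]
      al[, nm] <- ifelse(cfg[, j] == 0, g[ch[j], "mat"], g[ch[j], "pat"])
    }
    list(al = al, prob = prob)
  }

  chrs <- unique(map$chromosome)
  if (is_male) chrs <- setdiff(chrs, "X")
  al <- matrix(character(0), nrow = 1L, ncol = 0L)
  prob <- 1
  for (chr in chrs) {
    blk <- chrom_block(which(map$chromosome == chr))
    ia <- rep(seq_len(nrow(al)), times = nrow(blk$al))
    ib <- rep(seq_len(nrow(blk$al)), each = nrow(al))
    al <- cbind(al[ia, , drop = FALSE], blk$al[ib, , drop = FALSE])
    prob <- prob[ia] * blk$prob[ib]
  }

  xidx <- which(map$chromosome == "X")
  if (is_male) {
    r <- nrow(al)
    xal <- matrix(rep(g[xidx, "mat"], each = r), nrow = r,
                  dimnames = list(NULL, map$name[xidx]))
    xno <- matrix(NULLO, nrow = r, ncol = length(xidx),
                  dimnames = list(NULL, map$name[xidx]))
    al <- rbind(cbind(al, xal), cbind(al, xno))
    prob <- c(prob, prob) * 0.5
    xb <- rep(c(TRUE, FALSE), each = r)
  } else {
    xb <- rep(TRUE, nrow(al))
  }
  al <- al[, map$name, drop = FALSE]

  key <- apply(cbind(al, xb), 1L, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(prob, key)
    keep <- !duplicated(key)
    prob <- as.numeric(agg[match(key[keep], rownames(agg)), ])
    al <- al[keep, , drop = FALSE]
    xb <- xb[keep]
  }
  list(alleles = al, x_bearing = xb, prob = prob)
}

## Ordered (phase-preserving) offspring distribution: maternal and paternal
## alleles kept separate so linkage phase survives for chained crosses.
enumerate_offspring_ordered <- function(spec, map,
                                        map_function = c("morgan", "haldane")) {
  stopifnot(inherits(spec, "cross_spec"))
  map_function <- match.arg(map_function)
  seg <- union(het_loci(spec$mother, map),
               if (is.null(spec$father)) integer(0)
               else het_loci(spec$father, map))
  if (length(seg) > MAX_SEGREGATING) {
    ws_stop(sprintf("cannot enumerate: %d segregating loci (max %d)",
                    length(seg), MAX_SEGREGATING),
            class = "ws_capacity_error")
  }
  tm <- enumerate_gametes(spec$mother, map, map_function)
  tf <- if (is.null(spec$father)) tm
        else enumerate_gametes(spec$father, map, map_function)
  ia <- rep(seq_along(tm$prob), times = length(tf$prob))
  ib <- rep(seq_along(tf$prob), each = length(tm$prob))
  mat <- tm$alleles[ia, , drop = FALSE]
  pat <- tf$alleles[ib, , drop = FALSE]
  prob <- tm$prob[ia] * tf$prob[ib]
  sex <- if (is.null(spec$father)) rep("hermaphrodite", length(prob))
         else ifelse(tf$x_bearing[ib], "hermaphrodite", "male")

  key <- paste(apply(mat, 1L, paste, collapse = "\r"),
               apply(pat, 1L, paste, collapse = "\r"), sex, sep = "\n")
  keep <- !duplicated(key)
  agg <- rowsum(prob, key)
  prob <- as.numeric(agg[match(key[keep], rownames(agg)), ])
  list(mat = mat[keep, , drop = FALSE], pat = pat[keep, , drop = FALSE],
       sex = sex[keep], prob = prob)
}

#' Exact offspring genotype-class distribution of a cross
#'
#' Enumerates the offspring distribution exactly (the brute-force oracle for
#' [cross()]). Genotype classes are unordered (`A/a` is the same class as
#' `a/A`), matching Mendelian-ratio conventions; male X-linked classes show
#' the absent X as `"O"`. Feasible for up to 12 segregating loci.
#'
#' @param spec A [cross_spec()] (`offspring_count` is ignored).
#' @param map The [genetic_map()].
#' @param map_function Passed to [recombination_fraction()].
#' @return A data frame of class `"offspring_distribution"`: one column per
#'   locus (sorted `"a/b"` class keys), `sex`, and `prob`. Probabilities sum
#'   to 1 over all classes and sexes.
#' @examples
#' gm <- genetic_map(locus("sef-1", "II", 5))
#' h <- hermaphrodite(gm, list("sef-1" = c("m1", "+")))
#' enumerate_offspring_distribution(cross_spec(h), gm)
#' @export
enumerate_offspring_distribution <- function(spec, map,
                                             map_function = c("morgan", "haldane")) {
  ord <- enumerate_offspring_ordered(spec, map, map_function)
  keys <- vapply(seq_len(ncol(ord$mat)), function(j) {
    paste(pmin(ord$mat[, j], ord$pat[, j]),
          pmax(ord$mat[, j], ord$pat[, j]), sep = "/")
  }, character(length(ord$prob)))
  if (length(ord$prob) == 1L) keys <- matrix(keys, nrow = 1L)
  colnames(keys) <- colnames(ord$mat)
  df <- data.frame(keys, sex = ord$sex, check.names = FALSE,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(prob = ord$prob), by = df, FUN = sum)
  agg <- agg[order(-agg$prob), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("offspring_distribution", "data.frame")
  agg
}

#' Exact phenotype distribution of a cross
#'
#' Pushes the exact offspring distribution through a [phenotype_rule()].
#' Probabilities are reported conditionally within each sex class (they sum
#' to 1 per sex), which is how cross-progeny are scored at the bench:
#' hermaphrodite and male progeny are tallied separately.
#'
#' @inheritParams enumerate_offspring_distribution
#' @param rule A [phenotype_rule()].
#' @return A data frame with columns `sex`, `phenotype`, `probability`
#'   (conditional within sex) and `sex_prob` (the sex class probability).
#' @export
phenotype_frequencies <- function(spec, rule, map,
                                  map_function = c("morgan", "haldane")) {
  stopifnot(inherits(rule, "phenotype_rule"))
  ord <- enumerate_offspring_ordered(spec, map, map_function)
  lab <- vapply(seq_along(ord$prob), function(i) {
    g <- rbind(mat = ord$mat[i, ], pat = ord$pat[i, ])
    g <- t(g)
    rownames(g) <- colnames(ord$mat)
    colnames(g) <- c("mat", "pat")
    class(g) <- c("genotype", class(g))
    classify_phenotype(rule, g)
  }, character(1))
  agg <- stats::aggregate(
    list(prob = ord$prob),
    by = data.frame(sex = ord$sex, phenotype = lab, stringsAsFactors = FALSE),
    FUN = sum)
  sex_tot <- tapply(agg$prob, agg$sex, sum)
  agg$probability <- agg$prob / as.numeric(sex_tot[agg$sex])
  agg$sex_prob <- as.numeric(sex_tot[agg$sex])
  agg$prob <- NULL
  agg[order(agg$sex, -agg$probability), , drop = FALSE]
}
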