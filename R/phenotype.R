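# Growth-rate and pump-rate phenotype models.

#' Growth rate from food-exhaustion time
#'
#' Growth rate is defined as the inverse of the time a small founding
#' population needs to consume all food on a plate: five founders that
#' exhaust a plate in 7 days grow at 1/7 per day; a strain taking three
#' weeks grows at one third of that rate.
#'
#' @param days_to_exhaustion Positive time in days (vectorized).
#' @return Rate(s) in 1/day.
#' @examples
#' growth_rate(7)
#' growth_rate(21) / growth_rate(7)   # one third
#' @export
growth_rate <- function(days_to_exhaustion) {
  if (any(!is.finite(days_to_exhaustion)) || any(days_to_exhaustion <= 0)) {
    ws_stop("`days_to_exhaustion` must be positive")
  }
  1 / days_to_exhaustion
}

#' Predicted growth-rate ratio from effective brood sizes
#'
#' Exponential population growth at brood size B per generation gives a
#' growth rate proportional to ln(B): the food on a plate is exhausted
#' after about `log(food)/log(B)` generations, so the time to exhaustion
#' scales as `1/ln(B)`. The predicted fold-change in growth rate between
#' two strains is therefore `ln(B1)/ln(B2)` -- e.g. a drop in effective
#' brood size from 300 to 7 predicts roughly a threefold drop in growth
#' rate, not a fortyfold one.
#'
#' @param B1,B2 Effective brood sizes (`> 1`, so the logs are positive).
#' @return The predicted growth-rate ratio `ln(B1)/ln(B2)`.
#' @examples
#' relative_growth_factor(300, 7)   # about 2.93
#' @export
relative_growth_factor <- function(B1, B2) {
  if (any(c(B1, B2) <= 1) || any(!is.finite(c(B1, B2)))) {
    ws_stop("brood sizes must be finite and > 1")
  }
  log(B1) / log(B2)
}

#' Compare phenotype measurements across genotype groups
#'
#' Group-comparison statistics for per-worm phenotype data (terminal-bulb
#' pumps per minute, growth rates):
#'
#' * `"two_group"`: Welch two-sample t test between the two levels of
#'   `group`.
#' * `"one_way_vs_control"`: every non-control group compared against the
#'   named control, with familywise adjustment (`"bonferroni"` by default;
#'   `"dunnett"` uses multcomp when installed).
#' * `"two_way_factorial"`: two-way ANOVA with interaction on the two
#'   binary factors, plus an epistasis call: the genetic-interaction
#'   pattern in which the double mutant is no more extreme than either
#'   single mutant, indicating a shared pathway. The call requires (a) a
#'   significant interaction term, (b) a negative interaction contrast
#'   (double mutant below the additive expectation of the singles), and
#'   (c) a double-mutant mean not significantly exceeding the larger
#'   single-mutant mean (one-sided Welch test at `alpha`; a sharp sample
#'   mean comparison would fail half the time when the true means
#'   coincide).
#'
#' @param data Data frame of per-individual observations.
#' @param design One of `"two_group"`, `"one_way_vs_control"`,
#'   `"two_way_factorial"`.
#' @param response Name of the numeric response column.
#' @param group Name of the grouping column (first two designs).
#' @param control Control group label (`one_way_vs_control`).
#' @param factor_a,factor_b Names of the two binary factor columns
#'   (`two_way_factorial`); each must have exactly two levels. The
#'   wild-type (reference) level is `ref_a`/`ref_b` when given, otherwise
#'   `"+"` if present, otherwise the first factor level.
#' @param ref_a,ref_b Optional wild-type level of each factor.
#' @param alpha Significance level for the epistasis call.
#' @param adjust Familywise adjustment for `one_way_vs_control`.
#' @return A list of class `"group_comparison"`; contents depend on the
#'   design (see Details above). The factorial design returns `anova`
#'   (the aov summary table), `p_interaction`, `cell_means`,
#'   `interaction_contrast` and `epistasis` (`call`, plus the reasons).
#' @examples
#' set.seed(1)
#' d <- data.frame(value = c(rnorm(6, 10), rnorm(6, 14)),
#'                 group = rep(c("a", "b"), each = 6))
#' compare_groups(d, "two_group", response = "value", group = "group")
#' @export
compare_groups <- function(data,
                           design = c("two_group", "one_way_vs_control",
                                      "two_way_factorial"),
                           response = "value", group = "group",
                           control = NULL, factor_a = NULL, factor_b = NULL,
                           ref_a = NULL, ref_b = NULL, alpha = 0.05,
                           adjust = c("bonferroni", "dunnett")) {
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  if (!response %in% names(data)) ws_stop("`response` column not found")
  y <- data[[response]]
  if (!is.numeric(y)) ws_stop("the response must be numeric")

  if (design == "two_group") {
    g <- factor(data[[group]])
    if (nlevels(g) != 2L) ws_stop("`two_group` needs exactly two groups")
    if (any(table(g) < 2L)) ws_stop("need >= 2 observations per group")
    ht <- stats::t.test(y ~ g)
    return(structure(list(design = design,
                          groups = levels(g),
                          statistic = unname(ht$statistic),
                          df = unname(ht$parameter),
                          p = ht$p.value,
                          means = tapply(y, g, mean)),
                     class = "group_comparison"))
  }

  if (design == "one_way_vs_control") {
    g <- factor(data[[group]])
    if (is.null(control) || !control %in% levels(g)) {
      ws_stop("`control` must name one of the groups")
    }
    if (any(table(g) < 2L)) ws_stop("need >= 2 observations per group")
    others <- setdiff(levels(g), control)
    if (adjust == "dunnett" && requireNamespace("multcomp", quietly = TRUE)) {
      g2 <- stats::relevel(g, ref = control)
      fit <- stats::aov(y ~ g2)
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(g2 = "Dunnett"))
      sm <- summary(gl)
      comp <- data.frame(group = others,
                         estimate = as.numeric(sm$test$coefficients),
                         p_adj = as.numeric(sm$test$pvalues),
                         stringsAsFactors = FALSE)
    } else {
      if (adjust == "dunnett") {
        warning("multcomp not available; falling back to Bonferroni")
      }
      comp <- do.call(rbind, lapply(others, function(lv) {
        ht <- stats::t.test(y[g == lv], y[g == control])
        data.frame(group = lv,
                   estimate = mean(y[g == lv]) - mean(y[g == control]),
                   p_raw = ht$p.value, stringsAsFactors = FALSE)
      }))
      comp$p_adj <- pmin(1, comp$p_raw * length(others))
    }
    return(structure(list(design = design, control = control,
                          comparisons = comp,
                          means = tapply(y, g, mean)),
                     class = "group_comparison"))
  }

  ## two-way factorial
  if (is.null(factor_a) || is.null(factor_b) ||
      !all(c(factor_a, factor_b) %in% names(data))) {
    ws_stop("`factor_a` and `factor_b` columns are required")
  }
  as_wt_first <- function(x, ref) {
    x <- factor(x)
    if (is.null(ref)) ref <- if ("+" %in% levels(x)) "+" else levels(x)[1L]
    if (!ref %in% levels(x)) ws_stop("reference level not found in factor")
    stats::relevel(x, ref = ref)
  }
  A <- as_wt_first(data[[factor_a]], ref_a)
  B <- as_wt_first(data[[factor_b]], ref_b)
  if (nlevels(A) != 2L || nlevels(B) != 2L) {
    ws_stop("both factors must have exactly two levels")
  }
  cells <- table(A, B)
  if (any(cells < 2L)) {
    ws_stop("the factorial design must be fully crossed with >= 2 per cell")
  }
  fit <- stats::aov(y ~ A * B)
  tab <- summary(fit)[[1L]]
  p_int <- tab[grep("A:B", rownames(tab)), "Pr(>F)"]
  if (length(p_int) != 1L || is.nan(p_int) || stats::var(y) == 0) {
    p_int <- NA_real_
  }
  mu <- tapply(y, list(A, B), mean)
  ## rows/cols ordered by factor levels: [1,1] wild type, [2,2] double mutant
  contrast <- mu[2L, 2L] - mu[2L, 1L] - mu[1L, 2L] + mu[1L, 1L]
  degenerate <- is.na(p_int)   # zero residual variance etc.
  y_ab <- y[A != levels(A)[1L] & B != levels(B)[1L]]
  y_big <- if (mu[2L, 1L] >= mu[1L, 2L]) {
    y[A != levels(A)[1L] & B == levels(B)[1L]]
  } else {
    y[A == levels(A)[1L] & B != levels(B)[1L]]
  }
  p_exceed <- tryCatch(
    stats::t.test(y_ab, y_big, alternative = "greater")$p.value,
    error = function(e) if (mean(y_ab) <= mean(y_big)) 1 else 0)
  double_capped <- p_exceed > alpha
  call_epistasis <- !degenerate && p_int < alpha && contrast < 0 &&
    double_capped
  structure(list(design = design, anova = tab,
                 p_interaction = if (degenerate) NA_real_ else p_int,
                 cell_means = mu,
                 interaction_contrast = contrast,
                 epistasis = list(call = call_epistasis,
                                  significant = !degenerate && p_int < alpha,
                                  negative_interaction = contrast < 0,
                                  double_not_exceeding = double_capped,
                                  alpha = alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s>\n", x$design))
  if (x$design == "two_group") {
    cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n", x$statistic, x$df, x$p))
  } else if (x$design == "one_way_vs_control") {
    cat(sprintf("  vs control '%s':\n", x$control))
    print(x$comparisons, row.names = FALSE, digits = 4)
  } else {
    cat(sprintf("  interaction p = %.3g, contrast = %.3f; epistasis call: %s\n",
                x$p_interaction, x$interaction_contrast,
                x$epistasis$call))
  }
  invisible(x)
}

#' Write a group-comparison summary as JSON
#'
#' @param x A `"group_comparison"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(x, path) {
  stopifnot(inherits(x, "group_comparison"))
  out <- unclass(x)
  out$anova <- NULL
  out$cell_means <- if (!is.null(out$cell_means)) as.vector(out$cell_means)
  out$means <- if (!is.null(out$means)) as.list(out$means)
  jsonlite::write_json(out, path, auto_unbox = TRUE, na = "null",
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
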