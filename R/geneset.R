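#' Gene-wise Z-scaling across units
#'
#' Centers and unit-variance scales each gene (column) across all units
#' (rows) jointly — grouping happens after scaling, never before.
#' Zero-variance genes map to 0 and are flagged.
#'
#' @param values Units x genes numeric matrix (unit = sample or cell).
#' @return A `z_matrix`: the scaled matrix with attributes `center`, `scale`
#'   (per gene) and `zero_variance` (logical per gene).
#' @export
zscale <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) cs_stop("zscale needs at least 2 units")
  ctr <- colMeans(values)
  sdv <- apply(values, 2, sd)
  zero_var <- sdv == 0 | !is.finite(sdv)
  sdv_use <- ifelse(zero_var, 1, sdv)
  z <- sweep(sweep(values, 2, ctr), 2, sdv_use, "/")
  z[, zero_var] <- 0
  structure(z, center = ctr, scale = ifelse(zero_var, NA_real_, sdv),
            zero_variance = zero_var, class = c("z_matrix", "matrix", "array"))
}

#' Gene-set enrichment score with Wilcoxon test
#'
#' With `unit = "gene"` (bulk convention): each gene's score in a group is
#' its mean Z across that group's units; groups are compared by a paired
#' (by gene) Wilcoxon signed-rank test across the set's genes. With
#' `unit = "cell"` (single-cell convention): each cell's score is its mean Z
#' over the set's genes; the two groups of cells are compared by an
#' unpaired Wilcoxon rank-sum test. Set genes absent from the matrix are
#' ignored and counted.
#'
#' @param z A `z_matrix` (units x genes).
#' @param set Character vector of gene ids.
#' @param unit `"gene"` or `"cell"`.
#' @param groups Character/factor per unit; exactly 2 groups.
#' @param set_name Label carried into the result.
#' @return An `enrichment_result`: set name, unit, per-unit scores by group,
#'   group means, test tag, statistic, two-sided p, `n_missing_genes`.
#' @export
score_set <- function(z, set, unit = c("cell", "gene"), groups,
                      set_name = "set") {
  unit <- match.arg(unit)
  stopifnot(inherits(z, "z_matrix") || is.matrix(z))
  if (length(groups) != nrow(z))
    cs_stop("groups must have one label per unit (row)")
  lv <- unique(as.character(groups))
  if (length(lv) != 2L) cs_stop("need exactly 2 groups (got %d)", length(lv))
  present <- intersect(unique(set), colnames(z))
  n_missing <- length(unique(set)) - length(present)
  if (length(present) < 3L)
    cs_stop("fewer than 3 set genes present in the matrix (%d)",
            length(present))
  ga <- groups == lv[1]; gb <- groups == lv[2]
  if (unit == "gene") {
    score_a <- colMeans(z[ga, present, drop = FALSE])
    score_b <- colMeans(z[gb, present, drop = FALSE])
    wt <- wilcoxon_signed_rank(score_b - score_a)
    scores <- list(score_a, score_b)
    test <- "wilcoxon_paired"
  } else {
    sc <- rowMeans(z[, present, drop = FALSE])
    score_a <- sc[ga]; score_b <- sc[gb]
    wt <- wilcoxon_rank_sum(score_a, score_b, mode = "auto")
    scores <- list(score_a, score_b)
    test <- "wilcoxon_unpaired"
  }
  structure(list(set = set_name, unit = unit, groups = lv,
                 scores = setNames(scores, lv),
                 group_means = setNames(c(mean(score_a), mean(score_b)), lv),
                 mean_diff = mean(score_b) - mean(score_a),
                 test = test, statistic = wt$statistic,
                 p_value = wt$p_value, n_genes = length(present),
                 n_missing_genes = n_missing),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result '%s' (unit %s, %d genes): mean %s = %.4g, %s = %.4g; %s p = %.3g\n",
    x$set, x$unit, x$n_genes, x$groups[1], x$group_means[1], x$groups[2],
    x$group_means[2], x$test, x$p_value))
  invisible(x)
}

#' Boxplot summary statistics
#'
#' Quartiles by the linear-interpolation (type 7) convention; whiskers
#' extend to the most extreme observations within 1.5 IQR of the quartiles;
#' points beyond the whiskers are outliers.
#'
#' @param values Non-empty numeric vector.
#' @return list(q1, median, q3, whisker_low, whisker_high, outliers).
#' @export
boxplot_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) cs_stop("need at least one finite value")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Per-set correlation of effects between two contrasts
#'
#' For each gene set, the coefficient of determination (R^2) of the least-
#' squares fit of `effB` on `effA` over the set's genes present in both
#' effect vectors. Sets with fewer than 3 shared genes are skipped with a
#' warning. If categories are attached to the collection, the R^2
#' distributions of each category pair are compared by a two-sided
#' rank-sum test.
#'
#' @param effA,effB Named numeric vectors of per-gene effects (e.g. log2
#'   fold-changes) sharing a gene namespace.
#' @param sets A [gene_set_collection].
#' @return A data.frame (class `set_correlation`): set, n_genes, r_squared,
#'   category; category tests in attribute `category_tests`.
#' @export
foldchange_correlation <- function(effA, effB, sets) {
  if (is.null(names(effA)) || is.null(names(effB)))
    cs_stop("effect vectors must be named by gene")
  shared_ns <- intersect(names(effA), names(effB))
  if (!length(shared_ns)) cs_stop("effect vectors share no gene namespace")
  category <- attr(sets, "category")
  rows <- lapply(names(sets), function(nm) {
    g <- intersect(sets[[nm]], shared_ns)
    if (length(g) < 3L) {
      warning(sprintf("set '%s' has %d shared genes (<3); skipped", nm,
                      length(g)))
      return(NULL)
    }
    a <- effA[g]; b <- effB[g]
    r2 <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)^2
    data.frame(set = nm, n_genes = length(g), r_squared = r2,
               category = if (!is.null(category) && nm %in% names(category))
                 category[[nm]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) cs_stop("no set has >= 3 shared genes")
  cats <- unique(out$category[!is.na(out$category)])
  if (length(cats) >= 2L) {
    combs <- utils::combn(cats, 2, simplify = FALSE)
    tests <- lapply(combs, function(cp) {
      wt <- wilcoxon_rank_sum(out$r_squared[out$category == cp[1]],
                              out$r_squared[out$category == cp[2]],
                              mode = "auto")
      data.frame(category_a = cp[1], category_b = cp[2],
                 statistic = wt$statistic, p_value = wt$p_value,
                 stringsAsFactors = FALSE)
    })
    attr(out, "category_tests") <- do.call(rbind, tests)
  }
  class(out) <- c("set_correlation", "data.frame")
  out
}
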