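#' Tabulate cell-type composition by condition
#'
#' Builds the cell-type x condition contingency table feeding the abundance
#' shift test. Exactly two conditions are required; the first condition
#' column plays the "treatment/condition A" role (totals `m`), the second
#' the "control/condition B" role (totals `n`).
#'
#' @param assign A `cluster_assignment` with annotation (cell-type labels
#'   are used when present, raw cluster labels otherwise) or a character
#'   vector of per-cell types.
#' @param condition_label Character per cell.
#' @param conditions Optional length-2 ordering of the condition levels.
#' @return A `composition_table`: `counts` (types x 2), `m`, `n`, per-type
#'   `k` and `q`.
#' @export
tabulate_composition <- function(assign, condition_label,
                                 conditions = NULL) {
  types <- if (inherits(assign, "cluster_assignment")) {
    if (!is.null(assign$annotation))
      unname(assign$annotation[as.character(assign$labels)])
    else as.character(assign$labels)
  } else as.character(assign)
  if (!length(types)) cs_stop("empty assignment")
  if (length(types) != length(condition_label))
    cs_stop("condition_label length != number of cells")
  bad <- which(is.na(types) | is.na(condition_label))
  if (length(bad))
    cs_stop("unlabeled cells at positions: %s",
            paste(head(bad, 10), collapse = ", "))
  if (is.null(conditions)) conditions <- unique(condition_label)
  if (length(conditions) != 2L)
    cs_stop("need exactly 2 conditions (got %d)", length(conditions))
  counts <- table(factor(types), factor(condition_label,
                                        levels = conditions))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(list(counts = counts, conditions = conditions,
                 m = sum(counts[, 1]), n = sum(counts[, 2]),
                 k = rowSums(counts), q = counts[, 1]),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("composition_table (%s: m = %d; %s: n = %d):\n",
              x$conditions[1], x$m, x$conditions[2], x$n))
  print(x$counts)
  invisible(x)
}

#' Hypergeometric tail probability
#'
#' `P(X <= q)` (lower) or `P(X >= q)` (upper) for X hypergeometric with `K`
#' successes in a population of `N`, `n_draw` draws. Computed in log space
#' via the exact distribution function.
#'
#' @param q Observed count.
#' @param K Successes in the population.
#' @param N Population size.
#' @param n_draw Number of draws.
#' @param tail `"lower"` or `"upper"`.
#' @return Probability.
#' @export
hypergeom_tail <- function(q, K, N, n_draw, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (K > N || n_draw > N || K < 0 || n_draw < 0)
    cs_stop("inconsistent urn: K = %d, N = %d, n_draw = %d", K, N, n_draw)
  if (q < 0 || q > min(K, n_draw))
    cs_stop("q = %d outside [0, min(K, n_draw) = %d]", q, min(K, n_draw))
  if (tail == "lower")
    exp(phyper(q, K, N - K, n_draw, lower.tail = TRUE, log.p = TRUE))
  else
    exp(phyper(q - 1, K, N - K, n_draw, lower.tail = FALSE, log.p = TRUE))
}

# two-sided exact p for a 2x2 table by the point-probability method:
# sum of hypergeometric point probabilities <= that of the observed count
hypergeom_twosided <- function(q, K, N, n_draw) {
  support <- max(0, n_draw - (N - K)):min(K, n_draw)
  lp <- dhyper(support, K, N - K, n_draw, log = TRUE)
  lobs <- dhyper(q, K, N - K, n_draw, log = TRUE)
  min(1, sum(exp(lp[lp <= lobs + 1e-7])))
}

# noncentral hypergeometric CDF terms: P_or(X <= q) for the conditional
# distribution of the 2x2 table cell given margins, odds ratio `or`
nchyper_cdf <- function(q, K, N, n_draw, log_or) {
  support <- max(0, n_draw - (N - K)):min(K, n_draw)
  lw <- dhyper(support, K, N - K, n_draw, log = TRUE) + support * log_or
  lw <- lw - max(lw)
  w <- exp(lw)
  sum(w[support <= q]) / sum(w)
}

#' Exact abundance-shift test for one cell type
#'
#' Builds the 2x2 table (type C vs rest, condition A vs B), reports the
#' sample cross-product odds ratio (Haldane 0.5 correction iff a zero cell
#' exists, flagged), a two-sided exact hypergeometric p-value (sum of point
#' probabilities no larger than the observed one), both one-sided tails,
#' and an exact conditional (noncentral hypergeometric inversion)
#' confidence interval for the odds ratio.
#'
#' @param table A `composition_table`.
#' @param cell_type Type to test.
#' @param level Confidence level.
#' @return A `shift_result`: cell_type, q, k, m, n, odds_ratio,
#'   haldane_corrected, ci_low, ci_high, p_value (two-sided), p_lower,
#'   p_upper, level.
#' @export
abundance_shift_test <- function(table, cell_type, level = 0.95) {
  stopifnot(inherits(table, "composition_table"))
  check_fraction(level, "level", lo_open = TRUE, hi_open = TRUE)
  if (!cell_type %in% rownames(table$counts))
    cs_stop("cell type '%s' not in table", cell_type)
  if (table$m == 0 || table$n == 0)
    cs_stop("a condition has zero total cells")
  q <- table$counts[cell_type, 1]
  k <- table$k[[cell_type]]
  m <- table$m; n <- table$n
  # 2x2: rows type/rest, cols condition A/B
  a <- q; b <- k - q; c_ <- m - q; d <- n - (k - q)
  zero <- any(c(a, b, c_, d) == 0)
  or <- if (zero) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else (a * d) / (b * c_)
  N <- m + n
  p_two <- hypergeom_twosided(q, k, N, m)
  p_lower <- hypergeom_tail(q, k, N, m, "lower")
  p_upper <- hypergeom_tail(q, k, N, m, "upper")
  alpha <- 1 - level
  support <- max(0, m - (N - k)):min(k, m)
  ci_low <- if (q == min(support)) 0 else {
    f <- function(lo) 1 - nchyper_cdf(q - 1, k, N, m, lo) - alpha / 2
    exp(uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root)
  }
  ci_high <- if (q == max(support)) Inf else {
    f <- function(lo) nchyper_cdf(q, k, N, m, lo) - alpha / 2
    exp(uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root)
  }
  structure(list(cell_type = cell_type, q = q, k = k, m = m, n = n,
                 odds_ratio = or, haldane_corrected = zero,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_two,
                 p_lower = p_lower, p_upper = p_upper, level = level),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    "shift_result '%s': q=%d k=%d m=%d n=%d  OR = %.3g [%.3g, %.3g] (%.0f%%), two-sided p = %.3g%s\n",
    x$cell_type, x$q, x$k, x$m, x$n, x$odds_ratio, x$ci_low, x$ci_high,
    100 * x$level, x$p_value,
    if (x$haldane_corrected) " (Haldane-corrected OR)" else ""))
  invisible(x)
}

#' Abundance-shift tests for every cell type in a table
#'
#' @param table A `composition_table`.
#' @param level Confidence level.
#' @param adjust Apply BH adjustment across cell types (off by default,
#'   matching common practice for these screens).
#' @return A data.frame, one row per cell type.
#' @export
composition_report <- function(table, level = 0.95, adjust = FALSE) {
  rows <- lapply(rownames(table$counts), function(ty) {
    r <- abundance_shift_test(table, ty, level)
    data.frame(cell_type = ty, q = r$q, k = r$k, m = r$m, n = r$n,
               odds_ratio = r$odds_ratio, ci_low = r$ci_low,
               ci_high = r$ci_high, p_value = r$p_value,
               p_lower = r$p_lower, p_upper = r$p_upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$adj_p <- bh_adjust(out$p_value)
  out
}

#' Hypergeometric overlap test for two gene sets
#'
#' Tests whether the overlap of two sets within a universe deviates from
#' the sampling-without-replacement null. Reports the observed overlap, its
#' expectation, the two-sided point-probability p, and the one-sided
#' enrichment (upper) tail.
#'
#' @param setA,setB Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible ids.
#' @return list(overlap, expected, p_two_sided, p_enrichment).
#' @export
overlap_test <- function(setA, setB, universe) {
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    cs_stop("sets must be subsets of the universe")
  q <- length(intersect(setA, setB))
  K <- length(setA); n_draw <- length(setB); N <- length(universe)
  list(overlap = q, expected = K * n_draw / N,
       p_two_sided = hypergeom_twosided(q, K, N, n_draw),
       p_enrichment = hypergeom_tail(q, K, N, n_draw, "upper"))
}
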