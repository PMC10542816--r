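# Pooled sseq-style NB parameters: size factors, per-gene means and
# moment-estimated dispersions shrunk toward a high quantile of the
# estimates (shrinkage weight from the spread of the per-gene estimates).
compute_sseq_params <- function(counts, zeta_quantile = 0.995) {
  n <- nrow(counts)
  totals <- Matrix::rowSums(counts)
  size_factors <- totals / median(totals[totals > 0])
  if (any(size_factors == 0)) size_factors[size_factors == 0] <- 1e-8
  norm <- as(Matrix::Diagonal(x = 1 / size_factors) %*% counts,
             "CsparseMatrix")
  mu <- Matrix::colSums(norm) / n
  ex2 <- Matrix::colSums(norm^2) / n
  v <- pmax(0, (ex2 - mu^2) * n / (n - 1))
  use <- mu > 0 & v > 0
  phi_mm <- numeric(length(mu))
  phi_mm[use] <- pmax(0, (n * v[use] - mu[use] * sum(1 / size_factors)) /
                        (mu[use]^2 * n))
  if (any(use)) {
    zeta_hat <- as.numeric(quantile(phi_mm[use], zeta_quantile, type = 7))
    phi_bar <- mean(phi_mm[use])
    num <- sum((phi_mm[use] - phi_bar)^2) / max(1, sum(use) - 1)
    den <- sum((phi_mm[use] - zeta_hat)^2) / max(1, sum(use) - 2)
    delta <- if (den > 0) num / den else 0
    delta <- min(1, max(0, delta))
    phi <- delta * zeta_hat + (1 - delta) * phi_mm
  } else {
    phi <- phi_mm; zeta_hat <- 0; delta <- 0
  }
  list(size_factors = size_factors, mean = mu, phi = phi, phi_mm = phi_mm,
       zeta_hat = zeta_hat, delta = delta)
}

# Two-sided NB exact test on the two group sums conditional on their total:
# sums over the partition outcomes whose joint NB probability does not
# exceed that of the observed split. mu/phi: pooled per-gene estimates;
# sa/sb: summed size factors per group.
nb_exact_test <- function(xa, xb, sa, sb, mu, phi) {
  n <- xa + xb
  if (n == 0 || mu <= 0) return(1)
  all_a <- 0:n
  log_pr <- function(x, s) {
    m <- s * mu
    if (phi > 0) dnbinom(x, size = s / phi, mu = m, log = TRUE)
    else stats::dpois(x, m, log = TRUE)
  }
  lp <- log_pr(all_a, sa) + log_pr(n - all_a, sb)
  lobs <- log_pr(xa, sa) + log_pr(xb, sb)
  more_extreme <- lp <= lobs + 1e-12
  denom <- max(lp) + log(sum(exp(lp - max(lp))))
  num <- max(lp[more_extreme]) +
    log(sum(exp(lp[more_extreme] - max(lp[more_extreme]))))
  min(1, exp(num - denom))
}

#' Cluster-marker testing by the sseq negative-binomial exact test
#'
#' Compares each gene between one cluster and all other cells. Genes with
#' overall size-factor-normalized mean below `min_mean` are excluded. Per
#' gene, a negative binomial with pooled mean and moment-shrunk dispersion
#' is assumed; the two-sided exact test conditions on the total count and
#' sums the probabilities of group splits no more likely than the observed
#' one. Fold-changes are computed from size-factor-normalized group sums
#' with pseudocount 1.
#'
#' @param m A [umi_matrix] (raw counts).
#' @param assign A `cluster_assignment` aligned to the matrix cells.
#' @param cluster_id Cluster label to contrast against the rest.
#' @param min_mean Overall normalized-mean floor for testing.
#' @param zeta_quantile Quantile of the moment dispersions used as the
#'   shrinkage target.
#' @return A `marker_table` data.frame: gene, cluster, lfc, mean_in,
#'   mean_out, p, adj_p (BH across tested genes), test = "sseq".
#' @export
sseq_exact_test <- function(m, assign, cluster_id, min_mean = 0.1,
                            zeta_quantile = 0.995) {
  stopifnot(inherits(m, "umi_matrix"))
  labels <- if (inherits(assign, "cluster_assignment")) assign$labels
  else assign
  stopifnot(length(labels) == nrow(m$counts))
  in_grp <- labels == cluster_id
  if (sum(in_grp) < 2L) cs_stop("cluster %s has fewer than 2 cells",
                                format(cluster_id))
  if (sum(!in_grp) < 1L) cs_stop("complement of cluster %s is empty",
                                 format(cluster_id))
  params <- compute_sseq_params(m$counts)
  keep <- params$mean >= min_mean
  sf <- params$size_factors
  sa <- sum(sf[in_grp]); sb <- sum(sf[!in_grp])
  xa <- Matrix::colSums(m$counts[in_grp, , drop = FALSE])
  xb <- Matrix::colSums(m$counts[!in_grp, , drop = FALSE])
  genes <- which(keep)
  p <- vapply(genes, function(g)
    nb_exact_test(xa[g], xb[g], sa, sb, params$mean[g], params$phi[g]), 0)
  mean_in <- xa[genes] / sa
  mean_out <- xb[genes] / sb
  lfc <- log2((1 + xa[genes]) / (1 + sa)) - log2((1 + xb[genes]) / (1 + sb))
  res <- data.frame(gene = m$gene_ids[genes], cluster = cluster_id,
                    lfc = lfc, mean_in = mean_in, mean_out = mean_out,
                    p = p, adj_p = bh_adjust(p), test = "sseq",
                    stringsAsFactors = FALSE)
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Wilcoxon rank-sum test with explicit mode control
#'
#' Midranks for ties. `exact` mode enumerates the permutation null (only
#' valid without ties, total n <= 16 by default policy); `normal-approx`
#' uses the normal approximation with tie and continuity correction.
#' `auto` picks exact when `n_x + n_y <= 16` and there are no ties.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"`, or `"normal-approx"`.
#' @return list(statistic = Mann-Whitney U of `x`, p_value = two-sided p,
#'   mode = mode used).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact",
                                             "normal-approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) cs_stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
                      auto = !ties && length(x) + length(y) <= 16L,
                      exact = TRUE, `normal-approx` = FALSE)
  if (use_exact && ties)
    cs_stop("exact mode is not defined with ties; use normal-approx")
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE,
                alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mode = if (use_exact) "exact" else "normal-approx")
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped (classical convention) and counted. Exact
#' enumeration of sign assignments when `n <= 20` without tied absolute
#' values; otherwise normal approximation with tie and continuity
#' correction. All-zero input returns p = 1 with a warning.
#'
#' @param d Numeric vector of paired differences.
#' @param mode `"auto"`, `"exact"`, or `"normal-approx"`.
#' @return list(statistic = V, p_value, n_zero, mode).
#' @export
wilcoxon_signed_rank <- function(d, mode = c("auto", "exact",
                                             "normal-approx")) {
  mode <- match.arg(mode)
  n_zero <- sum(d == 0)
  dd <- d[d != 0]
  if (!length(dd)) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_zero = n_zero, mode = "degenerate"))
  }
  ties <- anyDuplicated(abs(dd)) > 0
  use_exact <- switch(mode,
                      auto = !ties && length(dd) <= 20L,
                      exact = TRUE, `normal-approx` = FALSE)
  if (use_exact && ties)
    cs_stop("exact mode is not defined with tied |differences|")
  wt <- suppressWarnings(
    wilcox.test(dd, exact = use_exact, correct = TRUE,
                alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_zero = n_zero, mode = if (use_exact) "exact" else "normal-approx")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, order-aligned with
#' the input.
#'
#' @param p Numeric vector in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    cs_stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select marker rows by fold-change and adjusted significance
#'
#' Keeps rows with `lfc >= lfc_min` and `adj_p < alpha` (the marker rule,
#' read literally), sorted by decreasing lfc then increasing adjusted p.
#'
#' @param rows A `marker_table` (or data.frame with `lfc` and `adj_p`).
#' @param lfc_min Inclusive log2 fold-change floor.
#' @param alpha Strict adjusted-p ceiling.
#' @return The selected rows.
#' @export
select_markers <- function(rows, lfc_min = 2, alpha = 0.05) {
  if (!nrow(rows)) return(rows)
  stopifnot(all(c("lfc", "adj_p") %in% names(rows)))
  keep <- rows$lfc >= lfc_min & rows$adj_p < alpha
  out <- rows[keep, , drop = FALSE]
  out[order(-out$lfc, out$adj_p), , drop = FALSE]
}
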