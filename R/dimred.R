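#' Variable-gene selection by binned dispersion ("mvp")
#'
#' Dispersion is variance/mean per gene on the depth-normalized (pre-log)
#' scale. Genes are split into `n_bins` equal-frequency bins by mean; within
#' each bin the dispersion is Z-scaled; selected genes have mean within
#' `[mean_low, mean_high]` and dispersion Z above `z_cutoff`.
#'
#' @param nm A `normalized_matrix` (the pre-log scaled values are used).
#' @param n_bins Number of equal-frequency mean bins.
#' @param mean_low,mean_high Inclusive mean window.
#' @param z_cutoff Strict lower bound on the within-bin dispersion Z.
#' @return A `feature_selection`: data.frame `stats` (gene, mean, dispersion,
#'   z, bin, selected) plus `selected` gene ids, `method`, `params`.
#' @export
select_hvg_mvp <- function(nm, n_bins = 20L, mean_low = 0.0125,
                           mean_high = 2, z_cutoff = 0.9) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- normalized_linear(nm)
  n <- nrow(x)
  mu <- Matrix::colSums(x) / n
  ex2 <- Matrix::colSums(x^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  nonzero <- mu > 0
  if (sum(nonzero) < n_bins)
    cs_stop("need at least n_bins (%d) genes with nonzero mean", n_bins)
  disp <- ifelse(nonzero, v / mu, NA_real_)
  # equal-frequency binning on the nonzero-mean genes (sizes differ by <= 1)
  bin <- rep(NA_integer_, length(mu))
  ord <- order(mu[nonzero])
  sizes <- rep(floor(sum(nonzero) / n_bins), n_bins)
  extra <- sum(nonzero) - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin[which(nonzero)[ord]] <- rep(seq_len(n_bins), sizes)
  z <- rep(NA_real_, length(mu))
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b)
    mb <- mean(disp[idx]); sb <- sd(disp[idx])
    z[idx] <- if (is.na(sb) || sb == 0) 0 else (disp[idx] - mb) / sb
  }
  selected <- nonzero & !is.na(z) & mu >= mean_low & mu <= mean_high &
    z > z_cutoff
  stats <- data.frame(gene = nm$gene_ids, mean = mu, dispersion = disp,
                      z = z, bin = bin, selected = selected,
                      stringsAsFactors = FALSE)
  structure(list(stats = stats, selected = nm$gene_ids[selected],
                 method = "mvp",
                 params = list(n_bins = n_bins, mean_low = mean_low,
                               mean_high = mean_high, z_cutoff = z_cutoff,
                               scale = nm$meta$dispersion_scale)),
            class = "feature_selection")
}

#' Variable-gene selection by standardized variance ("vst")
#'
#' Fits a local (loess, span 0.3) regression of log10 variance on log10 mean
#' over genes with positive variance; standardizes each gene's values by its
#' observed mean and the fitted standard deviation, clipping at `clip_max`
#' (default `sqrt(n_cells)`); ranks genes by the variance of the clipped
#' standardized values and keeps the top `n_select`.
#'
#' @param x A [umi_matrix], `normalized_matrix`, or cells x genes matrix.
#' @param n_select Number of genes to select.
#' @param clip_max Clip bound for standardized values.
#' @param loess_span Span of the mean-variance trend fit.
#' @return A `feature_selection` with per-gene standardized variance.
#' @export
select_hvg_vst <- function(x, n_select = 2000L, clip_max = NULL,
                           loess_span = 0.3) {
  counts <- if (inherits(x, "umi_matrix")) x$counts
  else if (inherits(x, "normalized_matrix")) normalized_linear(x)
  else as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  gene_ids <- if (!is.null(colnames(counts))) colnames(counts)
  else sprintf("g%d", seq_len(ncol(counts)))
  n <- nrow(counts)
  if (n_select > ncol(counts))
    cs_stop("n_select (%d) exceeds the number of genes (%d)", n_select,
            ncol(counts))
  if (is.null(clip_max)) clip_max <- sqrt(n)
  mu <- Matrix::colSums(counts) / n
  ex2 <- Matrix::colSums(counts^2) / n
  v <- pmax(0, (ex2 - mu^2) * n / (n - 1))
  use <- v > 0 & mu > 0
  fit <- loess(log10(v[use]) ~ log10(mu[use]), span = loess_span,
               degree = 2)
  sd_fit <- rep(NA_real_, length(mu))
  sd_fit[use] <- sqrt(10^predict(fit, log10(mu[use])))
  # variance of clipped standardized values, computed per gene on nonzeros
  # plus the shared zero term to avoid densifying
  std_var <- numeric(length(mu))
  cts <- as(counts, "CsparseMatrix")
  p <- cts@p
  for (g in which(use)) {
    xs <- cts@x[(p[g] + 1L):p[g + 1L]]
    if (p[g + 1L] == p[g]) xs <- numeric()
    z_nz <- pmin(clip_max, pmax(-clip_max, (xs - mu[g]) / sd_fit[g]))
    z0 <- pmin(clip_max, pmax(-clip_max, (0 - mu[g]) / sd_fit[g]))
    n0 <- n - length(xs)
    s1 <- sum(z_nz) + n0 * z0
    s2 <- sum(z_nz^2) + n0 * z0^2
    std_var[g] <- (s2 - s1^2 / n) / (n - 1)
  }
  ord <- order(std_var, decreasing = TRUE)
  sel_idx <- head(ord, n_select)
  selected <- logical(length(mu)); selected[sel_idx] <- TRUE
  stats <- data.frame(gene = gene_ids, mean = mu, variance = v,
                      fitted_sd = sd_fit, std_variance = std_var,
                      selected = selected, stringsAsFactors = FALSE)
  structure(list(stats = stats, selected = gene_ids[sel_idx],
                 method = "vst",
                 params = list(n_select = n_select, clip_max = clip_max,
                               loess_span = loess_span)),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("feature_selection (%s): %d of %d genes selected\n",
              x$method, length(x$selected), nrow(x$stats)))
  invisible(x)
}

#' Principal component analysis of normalized expression
#'
#' Wraps `stats::prcomp` on the chosen genes with centering and unit-variance
#' scaling; zero-variance genes are dropped with a
#' warning when scaling.
#'
#' @param nm A `normalized_matrix` (log values are used) or a cells x genes
#'   matrix.
#' @param genes Gene ids (or indices) to use; default all.
#' @param center,scale Passed to `prcomp`.
#' @param n_components Number of components to retain.
#' @return An `embedding`: `scores` (cells x components), `loadings`
#'   (genes x components, orthonormal), `explained_variance`
#'   (non-increasing), `center`/`scale` flags, `genes`.
#' @export
run_pca <- function(nm, genes = NULL, center = TRUE, scale = TRUE,
                    n_components = 20L) {
  x <- if (inherits(nm, "normalized_matrix")) normalized_values(nm)
  else as.matrix(nm)
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("g%d", seq_len(ncol(x)))
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  if (nrow(x) < 2L) cs_stop("PCA needs at least 2 cells")
  if (scale) {
    vv <- apply(x, 2, var)
    if (any(vv == 0)) {
      warning(sprintf("dropping %d zero-variance gene(s) before scaling",
                      sum(vv == 0)))
      x <- x[, vv > 0, drop = FALSE]
    }
  }
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = center, scale. = scale, rank. = n_components)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance = pc$sdev[seq_len(n_components)]^2,
                 total_variance = sum(pc$sdev^2),
                 center = center, scale = scale, genes = colnames(x)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  ev <- x$explained_variance / x$total_variance
  cat(sprintf("embedding: %d cells x %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), ncol(x$scores), 100 * ev[1],
              100 * ifelse(length(ev) > 1, ev[2], NA)))
  invisible(x)
}

new_cluster_assignment <- function(labels, cell_ids, method, k, seed = NA,
                                   annotation = NULL, extra = list()) {
  structure(c(list(labels = as.integer(labels), cell_ids = cell_ids,
                   k = as.integer(k), method = method, seed = seed,
                   annotation = annotation), extra),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s, k = %d):\n", x$method, x$k))
  print(table(x$labels))
  if (!is.null(x$annotation)) {
    cat("annotation:\n")
    print(x$annotation)
  }
  invisible(x)
}

#' K-means clustering of an embedding
#'
#' Runs Lloyd's algorithm from `n_init` seeded random starts (centers drawn
#' from the cells) and returns the solution with the lowest within-cluster
#' sum of squares. Deterministic given `seed`.
#'
#' @param emb An `embedding` (or a cells x components score matrix).
#' @param k Number of clusters.
#' @param n_init Number of random starts.
#' @param seed Integer seed.
#' @return A `cluster_assignment` with `wss` (best objective) and
#'   `wss_all` (objective of every start).
#' @export
kmeans_cluster <- function(emb, k = 9L, n_init = 10L, seed = 1L) {
  x <- if (inherits(emb, "embedding")) emb$scores else as.matrix(emb)
  if (k < 1L) cs_stop("k must be >= 1")
  if (k > nrow(x)) cs_stop("k (%d) exceeds the number of cells (%d)", k,
                           nrow(x))
  with_seed(seed, {
    best <- NULL
    wss_all <- numeric(n_init)
    for (s in seq_len(n_init)) {
      centers <- x[sample.int(nrow(x), k), , drop = FALSE]
      fit <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
      wss_all[s] <- fit$tot.withinss
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    new_cluster_assignment(best$cluster, rownames(x), "kmeans", k,
                           seed = seed,
                           extra = list(wss = best$tot.withinss,
                                        wss_all = wss_all,
                                        centers = best$centers))
  })
}

#' Re-cluster one cluster into k2 subclusters
#'
#' Cells of `cluster_id` are re-partitioned by k-means into `k2` new labels
#' appended after the existing ones (label ids of other cells are
#' unchanged; the vacated id is retired, so labels need not be contiguous).
#'
#' @param emb The `embedding` the clustering was computed on.
#' @param assign A `cluster_assignment`.
#' @param cluster_id Label to split.
#' @param k2 Number of subclusters.
#' @param n_init,seed As in [kmeans_cluster].
#' @return A new `cluster_assignment`.
#' @export
subcluster <- function(emb, assign, cluster_id, k2 = 2L, n_init = 10L,
                       seed = 1L) {
  stopifnot(inherits(assign, "cluster_assignment"))
  x <- if (inherits(emb, "embedding")) emb$scores else as.matrix(emb)
  idx <- which(assign$labels == cluster_id)
  if (!length(idx)) cs_stop("cluster %s does not exist", format(cluster_id))
  if (length(idx) < k2)
    cs_stop("cluster %s has %d cells, fewer than k2 = %d", format(cluster_id),
            length(idx), k2)
  sub <- kmeans_cluster(x[idx, , drop = FALSE], k = k2, n_init = n_init,
                        seed = seed)
  labels <- assign$labels
  base <- max(labels)
  labels[idx] <- base + sub$labels
  new_cluster_assignment(labels, assign$cell_ids, assign$method,
                         k = length(unique(labels)), seed = assign$seed)
}

#' Shared-nearest-neighbor modularity clustering
#'
#' Builds a k-nearest-neighbor graph in embedding space (Euclidean), weights
#' each edge by the Jaccard overlap of the two cells' neighbor sets (each
#' set includes the cell itself), prunes edges with overlap below
#' `prune`, and partitions the graph by modularity-maximizing Louvain
#' community detection. Deterministic given `seed`.
#'
#' @param emb An `embedding` or score matrix.
#' @param k_neighbors Neighborhood size (>= 2).
#' @param prune Jaccard cutoff below which edges are dropped.
#' @param seed Integer seed (community detection).
#' @return A `cluster_assignment` (method `snn_modularity`).
#' @export
snn_cluster <- function(emb, k_neighbors = 20L, prune = 1 / 15, seed = 1L) {
  x <- if (inherits(emb, "embedding")) emb$scores else as.matrix(emb)
  n <- nrow(x)
  if (k_neighbors < 2L) cs_stop("k_neighbors must be >= 2")
  if (n <= k_neighbors)
    cs_stop("need more cells (%d) than k_neighbors (%d)", n, k_neighbors)
  d <- as.matrix(dist(x))
  # neighbor sets: self plus the k_neighbors - 1 nearest other cells
  nb <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    nb[i, ] <- ord[seq_len(k_neighbors)]  # ord[1] == i (distance 0)
  }
  nb_sets <- lapply(seq_len(n), function(i) sort(nb[i, ]))
  # candidate edges: (i, j) with j in kNN(i)
  ii <- rep(seq_len(n), each = k_neighbors)
  jj <- as.vector(t(nb))
  keep <- ii < jj
  ii <- ii[keep]; jj <- jj[keep]
  pairs <- unique(cbind(ii, jj))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- nb_sets[[pairs[r, 1]]]; b <- nb_sets[[pairs[r, 2]]]
    ov <- length(intersect(a, b))
    ov / (2 * k_neighbors - ov)
  }, 0)
  keep <- w >= prune & w > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
               weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comm <- with_seed(seed, igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  labels <- igraph::membership(comm)[as.character(seq_len(n))]
  new_cluster_assignment(labels, rownames(x), "snn_modularity",
                         k = length(unique(labels)), seed = seed,
                         extra = list(k_neighbors = k_neighbors,
                                      prune = prune))
}

#' Annotate clusters by reference marker sets
#'
#' Each gene is Z-scaled across cells; each cluster is annotated with the
#' reference set maximizing the cluster mean of the mean Z over the set's
#' genes present in the matrix. Ties go to the lexicographically first set
#' name and are flagged.
#'
#' @param nm A `normalized_matrix`.
#' @param assign A `cluster_assignment`.
#' @param reference A [gene_set_collection] of marker sets (set name =
#'   cell-type label).
#' @return The `cluster_assignment` with `annotation` (named character:
#'   cluster label -> set name) and `annotation_scores` (clusters x sets
#'   matrix) filled in; ties recorded in `annotation_ties`.
#' @export
annotate_clusters <- function(nm, assign, reference) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(assign, "cluster_assignment"),
            inherits(reference, "gene_set_collection"))
  x <- normalized_values(nm)
  z <- zscale(x)
  present <- lapply(reference, function(g) intersect(g, colnames(z)))
  if (!any(lengths(present) > 0))
    cs_stop("no reference gene present in the matrix")
  labs <- sort(unique(assign$labels))
  set_names <- names(reference)
  scores <- matrix(NA_real_, length(labs), length(set_names),
                   dimnames = list(as.character(labs), set_names))
  cell_scores <- vapply(present, function(g) {
    if (!length(g)) return(rep(NA_real_, nrow(z)))
    rowMeans(z[, g, drop = FALSE])
  }, numeric(nrow(z)))
  for (li in seq_along(labs)) {
    scores[li, ] <- colMeans(cell_scores[assign$labels == labs[li], ,
                                         drop = FALSE])
  }
  ann <- character(length(labs)); ties <- logical(length(labs))
  for (li in seq_along(labs)) {
    s <- scores[li, ]
    best <- max(s, na.rm = TRUE)
    cand <- sort(set_names[!is.na(s) & s == best])
    ann[li] <- cand[1]
    ties[li] <- length(cand) > 1
  }
  assign$annotation <- setNames(ann, as.character(labs))
  assign$annotation_scores <- scores
  assign$annotation_ties <- setNames(ties, as.character(labs))
  assign
}

#' One-dimensional density-shift comparison between conditions
#'
#' For marker-positive (masked) cells, compares the distribution of one
#' embedding axis between two conditions: Gaussian kernel densities
#' (Silverman's bandwidth) on a shared grid, the difference of medians, and
#' a two-sample Kolmogorov-Smirnov test.
#'
#' @param emb An `embedding` or score matrix.
#' @param axis Component index or name (e.g. 1 or "PC1").
#' @param cell_mask Logical per cell (marker-positive predicate).
#' @param condition_label Character per cell; exactly 2 conditions among
#'   masked cells.
#' @param n_grid Number of shared grid points.
#' @return A `density_shift`: per-condition values and densities, the
#'   shared grid, `median_diff` (second minus first condition),
#'   `ks_statistic`, `p_value`.
#' @export
density_shift_1d <- function(emb, axis = 1L, cell_mask, condition_label,
                             n_grid = 512L) {
  x <- if (inherits(emb, "embedding")) emb$scores else as.matrix(emb)
  vals <- x[, axis]
  stopifnot(length(cell_mask) == length(vals),
            length(condition_label) == length(vals))
  vals <- vals[cell_mask]
  cond <- condition_label[cell_mask]
  levels <- unique(cond)
  if (length(levels) != 2L)
    cs_stop("need exactly 2 conditions among masked cells (got %d)",
            length(levels))
  a <- vals[cond == levels[1]]; b <- vals[cond == levels[2]]
  if (length(a) < 10L || length(b) < 10L)
    cs_stop("need >= 10 masked cells per condition (got %d and %d)",
            length(a), length(b))
  rng <- range(vals)
  pad <- 3 * max(stats::bw.nrd0(a), stats::bw.nrd0(b))
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = n_grid)
  dens <- lapply(list(a, b), function(v)
    density(v, bw = "nrd0", from = min(grid), to = max(grid), n = n_grid)$y)
  ks <- suppressWarnings(ks.test(a, b))
  structure(list(conditions = levels, values = list(a, b), grid = grid,
                 densities = setNames(dens, levels),
                 median_diff = median(b) - median(a),
                 ks_statistic = unname(ks$statistic),
                 p_value = ks$p.value),
            class = "density_shift")
}

#' @export
print.density_shift <- function(x, ...) {
  cat(sprintf(
    "density_shift (%s vs %s): median diff %.4g, KS D = %.4g, p = %.3g\n",
    x$conditions[2], x$conditions[1], x$median_diff, x$ks_statistic,
    x$p_value))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
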