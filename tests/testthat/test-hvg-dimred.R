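test_that("mvp selection is calibrated on i.i.d. genes and finds inflation", {
  set.seed(7)
  nc <- 500; ng <- 2000
  cnt <- matrix(rpois(nc * ng, 1), nc, ng)
  m <- umi_matrix(cnt, sprintf("c%d", 1:nc), sprintf("g%d", 1:ng))
  fs <- select_hvg_mvp(normalize_log(m))
  expect_lt(abs(length(fs$selected) / ng - pnorm(0.9, lower.tail = FALSE)),
            0.05)
  # equal-frequency bins: sizes differ by <= 1
  sizes <- table(fs$stats$bin)
  expect_lte(diff(range(sizes)), 1)

  cnt2 <- cnt
  for (g in 1:100) cnt2[, g] <- rnbinom(nc, mu = 1, size = 1 / 0.8)
  m2 <- umi_matrix(cnt2, sprintf("c%d", 1:nc), sprintf("g%d", 1:ng))
  fs2 <- select_hvg_mvp(normalize_log(m2))
  recall <- mean(sprintf("g%d", 1:100) %in% fs2$selected)
  expect_gte(recall, 0.9)

  # constant matrix -> empty selection, no error
  mc <- umi_matrix(matrix(1, 30, 25), sprintf("c%d", 1:30),
                   sprintf("g%d", 1:25))
  expect_length(select_hvg_mvp(normalize_log(mc), n_bins = 5)$selected, 0L)
})

test_that("vst standardizes on-trend genes and ranks spiked variance first", {
  set.seed(8)
  nc <- 400; ng <- 2000
  # genes spread along a Poisson-like mean-variance trend (var = mean);
  # spiked genes keep their mean but have 10x the trend variance
  mu <- exp(runif(ng, log(0.5), log(50)))
  x <- vapply(seq_len(ng), function(g) rnorm(nc, mu[g], sqrt(mu[g])),
              numeric(nc))
  dimnames(x) <- list(sprintf("c%d", 1:nc), sprintf("g%d", 1:ng))
  spiked <- sprintf("g%d", 1:50)
  x[, spiked] <- vapply(1:50, function(g)
    rnorm(nc, mu[g], sqrt(10 * mu[g])), numeric(nc))
  fs <- select_hvg_vst(x, n_select = 100)
  expect_true(all(spiked %in% fs$selected))
  # genes on the common trend have standardized variance near 1
  on_trend <- fs$stats$std_variance[!fs$stats$gene %in% spiked]
  expect_lt(max(on_trend) / median(on_trend), 2)

  expect_identical(sort(select_hvg_vst(x, n_select = ng)$selected),
                   sort(colnames(x)))
  expect_error(select_hvg_vst(x, n_select = ng + 1), "exceeds")
})

test_that("PCA satisfies its closed-form and invariance properties", {
  # 2 cells: single nonzero component along the difference vector
  x <- rbind(c(1, 0, 2), c(3, 4, 0))
  emb <- run_pca(x, center = TRUE, scale = FALSE, n_components = 2)
  expect_equal(emb$explained_variance[1], sum((x[1, ] - x[2, ])^2) / 2,
               tolerance = 1e-10)
  d <- (x[2, ] - x[1, ]) / sqrt(sum((x[2, ] - x[1, ])^2))
  expect_equal(abs(sum(emb$loadings[, 1] * d)), 1, tolerance = 1e-10)

  set.seed(2)
  y <- matrix(rnorm(40 * 6), 40, 6)
  emb2 <- run_pca(y, scale = FALSE, n_components = 6)
  # completeness: scores %*% t(loadings) reconstructs the centered data
  recon <- emb2$scores %*% t(emb2$loadings)
  expect_equal(unname(recon), unname(scale(y, scale = FALSE)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # loadings orthonormal, variances non-increasing
  expect_equal(crossprod(emb2$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(emb2$explained_variance) <= 1e-12))

  # duplicating every cell leaves directions unchanged up to sign
  emb3 <- run_pca(rbind(y, y), scale = FALSE, n_components = 3)
  for (j in 1:3)
    expect_equal(abs(sum(emb3$loadings[, j] * emb2$loadings[, j])), 1,
                 tolerance = 1e-6)
  expect_error(run_pca(y[1, , drop = FALSE]), "2 cells")
})

test_that("k-means returns the best of its starts and recovers blobs", {
  blobs <- make_blobs(60, rbind(c(0, 0), c(8, 0), c(0, 8)), seed = 3)
  cl <- kmeans_cluster(blobs$x, k = 3, n_init = 10, seed = 5)
  expect_equal(adjusted_rand_index(cl$labels, blobs$labels), 1.0)
  expect_equal(cl$wss, min(cl$wss_all))
  expect_true(all(cl$wss <= cl$wss_all))

  one <- kmeans_cluster(blobs$x, k = 1, seed = 1)
  centered <- scale(blobs$x, scale = FALSE)
  expect_equal(one$wss, sum(centered^2), tolerance = 1e-8)
  expect_error(kmeans_cluster(blobs$x, k = 0), "k must be")
  # determinism
  cl2 <- kmeans_cluster(blobs$x, k = 3, n_init = 10, seed = 5)
  expect_identical(cl$labels, cl2$labels)
})

test_that("subclustering splits one cluster and leaves the rest alone", {
  blobs <- make_blobs(50, rbind(c(0, 0), c(10, 0), c(10, 1.5)), seed = 4)
  merged <- ifelse(blobs$labels == 1, 1L, 2L)  # blobs 2+3 mislabeled as one
  assign <- cryptshift:::new_cluster_assignment(merged,
                                                rownames(blobs$x),
                                                "kmeans", 2L)
  out <- subcluster(blobs$x, assign, cluster_id = 2L, k2 = 2, seed = 6)
  expect_identical(out$labels[merged == 1L], assign$labels[merged == 1L])
  sub <- out$labels[merged == 2L]
  expect_setequal(unique(sub), c(3L, 4L))
  expect_equal(adjusted_rand_index(sub, blobs$labels[merged == 2L]), 1.0)
  expect_error(subcluster(blobs$x, assign, cluster_id = 9L), "does not exist")

  two <- make_blobs(1, rbind(c(0, 0), c(5, 5)), seed = 1)
  a2 <- cryptshift:::new_cluster_assignment(c(1L, 1L), rownames(two$x),
                                            "kmeans", 1L)
  s2 <- subcluster(two$x, a2, 1L, k2 = 2, seed = 1)
  expect_length(unique(s2$labels), 2L)
  expect_true(all(table(s2$labels) == 1L))
})

test_that("SNN clustering separates disconnected blobs and is order-stable", {
  # neighborhoods span most of a blob, so each blob is one dense community
  blobs <- make_blobs(40, rbind(c(0, 0), c(50, 50)), sd = 0.5, seed = 9)
  cl <- snn_cluster(blobs$x, k_neighbors = 30, seed = 2)
  expect_equal(cl$k, 2L)
  expect_equal(adjusted_rand_index(cl$labels, blobs$labels), 1.0)

  perm <- withr::with_seed(1, sample(nrow(blobs$x)))
  cl_p <- snn_cluster(blobs$x[perm, ], k_neighbors = 30, seed = 2)
  expect_equal(adjusted_rand_index(cl_p$labels, blobs$labels[perm]), 1.0)
  expect_error(snn_cluster(blobs$x, k_neighbors = 1), "k_neighbors")
  expect_error(snn_cluster(blobs$x[1:10, ], k_neighbors = 15), "more cells")
})

test_that("annotation picks the maximizing marker set with lexicographic ties", {
  set.seed(10)
  nc <- 120
  cnt <- matrix(rpois(nc * 30, 4), nc, 30,
                dimnames = list(sprintf("c%d", 1:nc),
                                sprintf("g%d", 1:30)))
  labels <- rep(1:2, each = 60)
  cnt[labels == 1, 1:3] <- cnt[labels == 1, 1:3] * 4   # ILC2 markers up 4x
  cnt[labels == 2, 4:6] <- cnt[labels == 2, 4:6] * 4
  m <- umi_matrix(cnt)
  nm <- normalize_log(m)
  assign <- cryptshift:::new_cluster_assignment(labels, rownames(cnt),
                                                "kmeans", 2L)
  ref <- gene_set_collection(list(ILC2 = c("g1", "g2", "g3"),
                                  Tcell = c("g4", "g5", "g6")))
  ann <- annotate_clusters(nm, assign, ref)
  expect_identical(unname(ann$annotation), c("ILC2", "Tcell"))

  # identical sets tie -> lexicographically first, flagged
  ref2 <- gene_set_collection(list(Zed = c("g1", "g2", "g3"),
                                   Alpha = c("g1", "g2", "g3")))
  ann2 <- annotate_clusters(nm, assign, ref2)
  expect_identical(unname(ann2$annotation), c("Alpha", "Alpha"))
  expect_true(all(ann2$annotation_ties))

  ref3 <- gene_set_collection(list(Only = c("g1", "g2", "g3")))
  expect_identical(unique(unname(annotate_clusters(nm, assign,
                                                   ref3)$annotation)),
                   "Only")
  ref4 <- gene_set_collection(list(S = c("absent1", "absent2", "absent3")))
  expect_error(annotate_clusters(nm, assign, ref4), "no reference gene")
})

test_that("density shift reports null and shifted cases correctly", {
  set.seed(12)
  x <- matrix(rnorm(600), 600, 1)
  cond <- rep(c("a", "b"), each = 300)
  # identical samples: duplicate one condition's values
  x[cond == "b", 1] <- x[cond == "a", 1]
  ds <- density_shift_1d(x, 1, rep(TRUE, 600), cond)
  expect_equal(ds$median_diff, 0)
  expect_equal(ds$p_value, 1)
  # densities integrate to ~1 on the grid
  for (d in ds$densities) {
    expect_true(all(d >= 0))
    expect_lt(abs(sum(d) * diff(ds$grid[1:2]) - 1), 1e-3)
  }

  x2 <- matrix(c(rnorm(300), rnorm(300, 1)), ncol = 1)
  ds2 <- density_shift_1d(x2, 1, rep(TRUE, 600), cond)
  expect_lt(ds2$p_value, 0.01)
  expect_gt(ds2$median_diff, 0.5)

  expect_error(density_shift_1d(x2, 1, c(rep(TRUE, 300), rep(FALSE, 300)),
                                cond),
               "2 conditions")
})
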