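test_that("presets carry the expected type counts and reject unknown names", {
  expect_length(make_preset("immune9")$cell_types, 9L)
  expect_length(make_preset("crypt10")$cell_types, 10L)
  expect_length(make_preset("organoid7")$cell_types, 7L)
  expect_error(make_preset("blobs42"), "unknown preset")
  for (nm in c("crypt10", "immune9", "organoid7")) {
    spec <- make_preset(nm)
    expect_true(all(abs(colSums(spec$composition) - 1) < 1e-9))
    expect_true(all(spec$baseline_mean > 0))
    expect_true(all(unlist(lapply(spec$marker_map, `[[`, "genes")) %in%
                      spec$gene_ids))
  }
})

test_that("immune9 plants OR 3 and 5 with exact-null remaining types", {
  or <- true_odds_ratios(make_preset("immune9"))
  expect_equal(unname(or["ILC2"]), 3, tolerance = 1e-10)
  expect_equal(unname(or["CytotoxicT"]), 5, tolerance = 1e-10)
  expect_lt(or["NaiveT"], 1)  # depleted absorber
  nulls <- setdiff(names(or), c("ILC2", "CytotoxicT", "NaiveT"))
  expect_equal(unname(or[nulls]), rep(1, length(nulls)), tolerance = 1e-12)
})

test_that("simulation is deterministic and the empty case is valid", {
  spec <- make_preset("organoid7")
  spec$n_cells_per_condition <- 40L
  s1 <- simulate_counts(spec, 9)
  s2 <- simulate_counts(spec, 9)
  expect_identical(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))
  expect_identical(s1$truth$cells, s2$truth$cells)
  s3 <- simulate_counts(spec, 10)
  expect_false(identical(as.matrix(s1$matrix$counts),
                         as.matrix(s3$matrix$counts)))

  spec$n_cells_per_condition <- 0L
  s0 <- simulate_counts(spec, 1)
  expect_equal(nrow(s0$matrix$counts), 0L)
  expect_equal(ncol(s0$matrix$counts), length(spec$gene_ids))
  expect_equal(nrow(s0$truth$cells), 0L)
})

test_that("type frequencies fall inside exact binomial intervals", {
  spec <- make_preset("immune9")
  spec$cell_types <- c("A", "B")
  spec$composition <- cbind(c1 = c(0.5, 0.5), c2 = c(0.5, 0.5))
  rownames(spec$composition) <- c("A", "B")
  spec$conditions <- c("c1", "c2")
  spec$marker_map <- list(); spec$latent_axis <- NULL
  spec$n_cells_per_condition <- 5000L
  ct <- simulate_cell_types(spec, 3)
  n <- nrow(ct)
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(sum(ct$cell_type == "A"), ci[1])
  expect_lte(sum(ct$cell_type == "A"), ci[2])
})

test_that("marker fold-changes are realized on depth-normalized means", {
  spec <- make_preset("immune9")
  spec$n_cells_per_condition <- 2500L
  sim <- simulate_counts(spec, 5)
  m <- sim$matrix
  norm <- as.matrix(m$counts / Matrix::rowSums(m$counts))
  gene <- spec$marker_map$BCell$genes[1]
  inb <- sim$truth$cells$cell_type == "BCell"
  others <- !inb
  ratio <- mean(norm[inb, gene]) / mean(norm[others, gene])
  # lfc = 3 -> 8-fold over baseline on relative expression
  expect_gt(ratio, 6.5)
  expect_lt(ratio, 9.5)
})

test_that("counts are overdispersed when nb_dispersion > 0", {
  spec <- make_preset("immune9")
  spec$cell_types <- "A"
  spec$composition <- matrix(c(1, 1), 1, 2,
                             dimnames = list("A", spec$conditions))
  spec$marker_map <- list()
  spec$n_cells_per_condition <- 2500L
  # constant depth: degenerate log-normal
  spec$depth <- list(young = list(meanlog = log(2000), sdlog = 0),
                     old = list(meanlog = log(2000), sdlog = 0))
  sim <- simulate_counts(spec, 2)
  cnt <- as.matrix(sim$matrix$counts)
  mu <- colMeans(cnt)
  vm <- apply(cnt, 2, var) / pmax(mu, 1e-12)
  top <- order(mu, decreasing = TRUE)[1:100]  # well-measured genes
  expect_gt(mean(vm[top] > 1), 0.97)
})

test_that("latent axis aligns with PC1 of the affected genes (crypt10)", {
  spec <- make_preset("crypt10")
  spec$n_cells_per_condition <- 600L
  sim <- simulate_counts(spec, 21)
  nm <- normalize_log(sim$matrix)
  emb <- run_pca(nm, genes = spec$latent_axis$genes, n_components = 5)
  aff <- sim$truth$cells$cell_type %in% spec$latent_axis$cell_types
  cc <- cor(emb$scores[aff, 1], sim$truth$cells$latent[aff])
  expect_gte(abs(cc), 0.8)
})

test_that("hashtag generator honors rates and low-signal construction", {
  truth <- data.frame(cell_id = sprintf("c%05d", 1:10000))
  h <- simulate_hashtags(truth, n_tags = 4, doublet_rate = 0,
                         low_signal_rate = 0, background_fraction = 0.02,
                         seed = 8)
  top_frac <- apply(h$hashtags, 1, max) / rowSums(h$hashtags)
  expect_gte(mean(top_frac > 0.9), 0.99)

  h2 <- simulate_hashtags(truth[1:500, , drop = FALSE], n_tags = 3,
                          low_signal_rate = 1, seed = 8)
  expect_true(all(rowSums(h2$hashtags) < 10))

  h3 <- simulate_hashtags(truth, n_tags = 3, doublet_rate = 0.1, seed = 8)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(sum(h3$truth$doublet), ci[1])
  expect_lte(sum(h3$truth$doublet), ci[2])

  expect_error(simulate_hashtags(truth, background_fraction = 0.5, seed = 1),
               "not identifiable")
})
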