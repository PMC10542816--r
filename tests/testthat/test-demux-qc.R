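test_that("hashtag classification follows the read floor and presence rule", {
  hm <- rbind(c(9, 0, 0),     # below the 10-read floor
              c(100, 0, 0),   # pure single
              c(50, 50, 0),   # double at fraction 0.5
              c(10, 10, 10),  # triple
              c(40, 0, 2))    # single: tag3 below 0.2
  rownames(hm) <- sprintf("c%d", 1:5)
  h <- hashtag_counts(hm)
  dm <- classify_hashtags(h)
  expect_identical(dm$category,
                   c("low_signal", "single", "double", "triple", "single"))
  expect_identical(dm$tag, c(NA, "tag1", NA, NA, "tag1"))
  expect_equal(dm$top_fraction[2], 1.0)

  # partition: every cell gets exactly one category; singles carry >= floor
  expect_true(all(dm$category %in%
                    c("single", "double", "triple", "multiple", "low_signal")))
  expect_true(all(dm$total_reads[dm$category == "single"] >= 10))
  expect_error(classify_hashtags(h, presence_fraction = 0),
               "presence_fraction")
  # >= 4 present tags -> multiple
  h4 <- hashtag_counts(matrix(25, 1, 4, dimnames = list("c", paste0("t", 1:4))))
  expect_identical(classify_hashtags(h4)$category, "multiple")
})

test_that("downsampling hits the target median and never inflates counts", {
  set.seed(11)
  cnt <- matrix(rpois(400 * 30, 5), 400, 30)
  m <- umi_matrix(cnt, sprintf("c%d", 1:400), sprintf("g%d", 1:30),
                  sample_label = rep(c("s1", "s2"), each = 200))
  # push sample 1 to double depth
  cnt[1:200, ] <- cnt[1:200, ] * 2
  m <- umi_matrix(cnt, sprintf("c%d", 1:400), sprintf("g%d", 1:30),
                  sample_label = rep(c("s1", "s2"), each = 200))
  med <- tapply(Matrix::rowSums(m$counts), m$sample_label, median)
  d <- downsample_to_common_depth(m, seed = 3)
  med2 <- tapply(Matrix::rowSums(d$counts), d$sample_label, median)
  expect_lte(abs(med2[["s1"]] - min(med)), 1)
  expect_identical(med2[["s2"]], med[["s2"]])   # sample at target untouched
  expect_true(all((m$counts - d$counts)@x >= 0))

  # all mass in one gene: thinning is deterministic
  m1 <- toy_umi(rbind(c(4, 0, 0), c(4, 0, 0)))
  d1 <- downsample_to_common_depth(m1, seed = 1, target = 2)
  expect_identical(as.vector(as.matrix(d1$counts)[1, ]), c(2, 0, 0))

  # target equal to the median leaves the sample unchanged
  same <- downsample_to_common_depth(m1, seed = 1, target = 4)
  expect_identical(as.matrix(same$counts), as.matrix(m1$counts))
  expect_error(downsample_to_common_depth(m1, seed = 1, target = 0), "> 0")
})

test_that("per-cell thinning matches the hypergeometric marginal", {
  cell <- c(12, 8, 5)
  m <- toy_umi(matrix(cell, 1))
  draws <- vapply(1:2000, function(s) {
    d <- downsample_to_common_depth(m, seed = s, target = 10)
    as.matrix(d$counts)[1, 1]
  }, 0)
  expected <- dhyper(0:10, cell[1], sum(cell) - cell[1], 10) * 2000
  obs <- tabulate(draws + 1, nbins = 11)
  keep <- expected > 5
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("mito percentage handles edge cases", {
  cnt <- rbind(c(8, 92, 0), c(0, 0, 0), c(5, 5, 0))
  m <- umi_matrix(cnt, sprintf("c%d", 1:3), c("mt-a", "g1", "g2"))
  expect_equal(mito_percent(m), c(8, 0, 50))
  m2 <- umi_matrix(cnt, sprintf("c%d", 1:3), c("a", "g1", "g2"))
  expect_equal(mito_percent(m2), c(0, 0, 0))
})

test_that("QC filtering applies the stated boundary conventions", {
  # 7-cell fixture: exactly cells 1-3 pass the immune thresholds
  genes <- c(paste0("g", 1:2000), "mt-1")
  mk_cell <- function(n_genes, umi, mito) {
    x <- numeric(2001)
    per <- max(1, floor((umi - mito) / n_genes))
    x[seq_len(n_genes)] <- per
    x[1] <- x[1] + (umi - mito) - per * n_genes
    x[2001] <- mito
    x
  }
  cells <- rbind(
    mk_cell(200, 1000, 0),     # keep: 200 detected genes, floor inclusive
    mk_cell(1500, 3000, 0),    # keep: 1500 detected genes, ceiling inclusive
    mk_cell(800, 4999, 100),   # keep: UMI just under, mito 2%
    mk_cell(199, 1000, 0),     # drop: too few genes
    mk_cell(800, 5000, 100),   # drop: UMI = 5000 is strict
    mk_cell(800, 2000, 160),   # drop: mito = 8% is strict
    mk_cell(1501, 4000, 0))    # drop: too many genes
  m <- umi_matrix(cells, sprintf("c%d", 1:7), genes)
  th <- qc_thresholds(200L, 1500L, 5000, 8)
  f <- filter_cells_qc(m, th)
  expect_identical(f$cell_ids, c("c1", "c2", "c3"))
  rep <- attr(f, "qc_report")
  expect_equal(rep$n_out, 3L)
  # idempotent
  f2 <- filter_cells_qc(f, th)
  expect_identical(as.matrix(f2$counts), as.matrix(f$counts))
})

test_that("normalization scales totals to target then logs", {
  cnt <- rbind(c(50, 50, 0), c(100, 100, 0))
  m <- toy_umi(cnt)
  nm <- normalize_log(m)  # median target = 150
  lin <- as.matrix(normalized_linear(nm))
  expect_equal(unname(rowSums(lin)), c(150, 150))

  nm2 <- normalize_log(m, mode = "scale_to_target", target = 10000)
  v <- normalized_values(nm2)
  # count 1 in a cell of total 10000 at target 10000 -> log10(2)
  m3 <- toy_umi(matrix(c(1, 9999), 1))
  v3 <- normalized_values(normalize_log(m3, mode = "scale_to_target",
                                        target = 10000))
  expect_equal(v3[1, 1], log10(2), tolerance = 1e-12)
  # zeros map to log(pseudocount) = 0
  expect_equal(v[1, 3], 0)
  expect_error(normalize_log(m, pseudocount = 0), "pseudocount")
})
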