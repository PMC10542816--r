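# Independent brute-force oracles used against the package's statistics.

# Hypergeometric tails by literal subset enumeration: fix a K-subset of an
# N-element universe, enumerate every n_draw-subset, count overlaps.
enum_hyper_tail <- function(q, K, N, n_draw, tail) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- combn(N, n_draw)
  overlaps <- apply(draws, 2, function(s) sum(s %in% marked))
  if (tail == "lower") mean(overlaps <= q) else mean(overlaps >= q)
}

enum_hyper_twosided <- function(q, K, N, n_draw) {
  draws <- combn(N, n_draw)
  overlaps <- apply(draws, 2, function(s) sum(s %in% seq_len(K)))
  tab <- table(overlaps) / ncol(draws)
  p_obs <- tab[[as.character(q)]]
  sum(tab[tab <= p_obs + 1e-12])
}

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# sample to the x-positions (no ties assumed).
enum_rank_sum_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(n, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_lo <- mean(us <= u_obs); p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  p_lo <- mean(vs <= v_obs); p_hi <- mean(vs >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Tiny dense umi_matrix builder for hand fixtures.
toy_umi <- function(counts, mito = NULL, sample = "s1", condition = "c1") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("g%02d", seq_len(ncol(counts)))
  umi_matrix(counts, mito_flags = mito, sample_label = sample,
             condition_label = condition)
}

# Gaussian blob embedding with known labels.
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  k <- nrow(centers)
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(k), function(i)
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
    rownames(x) <- sprintf("b%04d", seq_len(nrow(x)))
    list(x = x, labels = rep(seq_len(k), each = n_per))
  })
}
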