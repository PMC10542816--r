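#' Classify cells by hashtag signal
#'
#' Cells with fewer than `min_reads` total hashtag reads are `low_signal`.
#' Otherwise a tag is "present" when its read fraction is at least
#' `presence_fraction`; one present tag makes the cell `single` (with that
#' tag assigned), two `double`, three `triple`, four or more `multiple`.
#' Only `single` cells are retained downstream.
#'
#' @param h A [hashtag_counts] matrix.
#' @param min_reads Total-read floor below which a cell is `low_signal`.
#' @param presence_fraction Fraction in (0, 1] above which a tag counts as
#'   present.
#' @return A `demux_result` data.frame: `cell_id`, `category`, `tag`
#'   (NA unless single), `top_fraction`, `total_reads`.
#' @export
classify_hashtags <- function(h, min_reads = 10L, presence_fraction = 0.2) {
  stopifnot(inherits(h, "hashtag_counts") || is.matrix(h))
  if (!nrow(h)) cs_stop("empty hashtag table")
  check_fraction(presence_fraction, "presence_fraction",
                 lo = 0, hi = 1, lo_open = TRUE)
  total <- rowSums(h)
  frac <- h / pmax(total, 1)
  n_present <- rowSums(frac >= presence_fraction & h > 0)
  top_idx <- max.col(frac, ties.method = "first")
  top_fraction <- frac[cbind(seq_len(nrow(h)), top_idx)]
  category <- ifelse(total < min_reads, "low_signal",
              ifelse(n_present <= 1L, "single",
              ifelse(n_present == 2L, "double",
              ifelse(n_present == 3L, "triple", "multiple"))))
  tag <- ifelse(category == "single", colnames(h)[top_idx], NA_character_)
  res <- data.frame(cell_id = rownames(h), category = category, tag = tag,
                    top_fraction = ifelse(total > 0, top_fraction, 0),
                    total_reads = as.integer(total),
                    stringsAsFactors = FALSE)
  class(res) <- c("demux_result", "data.frame")
  res
}

#' @export
print.demux_result <- function(x, ...) {
  cat("demux_result:\n")
  print(table(x$category))
  invisible(x)
}

# multivariate-hypergeometric thinning of one count vector to total `k`:
# draw k of the cell's UMIs without replacement
thin_cell <- function(counts_nz, k) {
  total <- sum(counts_nz)
  if (k >= total) return(counts_nz)
  if (k <= 0) return(integer(length(counts_nz)))
  drawn <- sample.int(total, k)
  breaks <- c(0L, cumsum(counts_nz))
  tabulate(findInterval(drawn, breaks, left.open = TRUE),
           nbins = length(counts_nz))
}

#' Downsample samples to a common median per-cell depth
#'
#' For each sample whose median per-cell total UMI exceeds the target, every
#' cell's counts are thinned without replacement (a multivariate
#' hypergeometric draw of `round(total * target / median_s)` of the cell's
#' UMIs). Samples at or below target are untouched; counts never increase.
#' The default target is the minimum per-sample median.
#'
#' @param m A [umi_matrix].
#' @param seed Integer seed for the thinning draws.
#' @param target Optional positive integer; must not exceed the minimum
#'   per-sample median.
#' @return A [umi_matrix] with thinned counts.
#' @export
downsample_to_common_depth <- function(m, seed, target = NULL) {
  stopifnot(inherits(m, "umi_matrix"))
  totals <- cell_totals(m)
  med <- tapply(totals, m$sample_label, median)
  if (is.null(target)) target <- min(med)
  if (target <= 0) cs_stop("target must be > 0")
  if (target > min(med))
    cs_stop("target (%g) exceeds the minimum per-sample median (%g)",
            target, min(med))
  tm <- as(m$counts, "TsparseMatrix")
  x <- tm@x
  row_of <- tm@i + 1L
  entries_by_row <- split(seq_along(x), row_of)
  with_seed(seed, {
    for (s in names(med)) {
      if (med[[s]] <= target) next
      rate <- target / med[[s]]
      for (i in which(m$sample_label == s)) {
        idx <- entries_by_row[[as.character(i)]]
        if (is.null(idx)) next
        k <- round(totals[i] * rate)
        x[idx] <- thin_cell(as.integer(x[idx]), k)
      }
    }
  })
  keep <- x > 0
  counts <- Matrix::sparseMatrix(i = row_of[keep], j = tm@j[keep] + 1L,
                                 x = x[keep], dims = dim(m$counts))
  umi_matrix(counts, m$cell_ids, m$gene_ids, m$mito_flags,
             m$sample_label, m$condition_label)
}

#' Per-cell mitochondrial count percentage
#'
#' @param m A [umi_matrix] with `mito_flags` set.
#' @return Numeric per cell: 100 * mito counts / total counts (0 for
#'   zero-total cells).
#' @export
mito_percent <- function(m) {
  stopifnot(inherits(m, "umi_matrix"))
  total <- cell_totals(m)
  mito <- if (any(m$mito_flags))
    Matrix::rowSums(m$counts[, m$mito_flags, drop = FALSE]) else
      numeric(nrow(m$counts))
  unname(ifelse(total > 0, 100 * mito / total, 0))
}

#' QC thresholds
#'
#' Boundary conventions: the detected-gene bounds are inclusive on both
#' ends, while the UMI and mitochondrial cutoffs are strict upper bounds.
#' The conventions are recorded in the object so downstream reports can
#' state them.
#'
#' @param min_genes,max_genes Inclusive detected-gene bounds.
#' @param max_umi Strict upper bound on total UMI (`Inf` to disable).
#' @param max_mito_pct Strict upper bound on mito percentage.
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 1500L,
                          max_umi = 5000, max_mito_pct = 8) {
  if (min_genes > max_genes) cs_stop("min_genes > max_genes")
  if (min_genes < 0 || max_umi < 0 || max_mito_pct < 0)
    cs_stop("thresholds must be >= 0")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_umi = max_umi, max_mito_pct = max_mito_pct,
                 boundary = c(genes = "inclusive", umi = "strict",
                              mito = "strict")),
            class = "qc_thresholds")
}

#' Filter cells by QC criteria
#'
#' Keeps cells with `min_genes <= detected genes <= max_genes` (inclusive),
#' total UMI strictly below `max_umi`, and mito percentage strictly below
#' `max_mito_pct`. The gene set is unchanged. Per-criterion removal counts
#' (of cells failing that criterion) are attached as attribute `qc_report`.
#'
#' @param m A [umi_matrix].
#' @param th A [qc_thresholds].
#' @return Filtered [umi_matrix] (possibly with zero cells).
#' @export
filter_cells_qc <- function(m, th) {
  stopifnot(inherits(m, "umi_matrix"), inherits(th, "qc_thresholds"))
  detected <- cells_detected_genes(m)
  total <- cell_totals(m)
  mito <- mito_percent(m)
  pass_genes <- detected >= th$min_genes & detected <= th$max_genes
  pass_umi <- total < th$max_umi
  pass_mito <- mito < th$max_mito_pct
  keep <- pass_genes & pass_umi & pass_mito
  out <- subset_umi(m, cells = keep)
  attr(out, "qc_report") <- list(
    n_in = nrow(m$counts), n_out = sum(keep),
    removed_genes = sum(!pass_genes), removed_umi = sum(!pass_umi),
    removed_mito = sum(!pass_mito), thresholds = th)
  out
}

#' Depth-normalize and log-transform counts
#'
#' Each cell's counts are scaled so its total equals a common target (the
#' median of per-cell totals for `scale_to_median`, or `target` for
#' `scale_to_target`), then `log(pseudocount + scaled)` in the chosen base.
#' Zero-total cells map to `log(pseudocount)` everywhere.
#'
#' @param m A [umi_matrix].
#' @param mode `"scale_to_median"` (default) or `"scale_to_target"`.
#' @param log_base 10 or `exp(1)`.
#' @param pseudocount Added before the log; must be > 0 when zeros exist.
#' @param target Required for `scale_to_target`.
#' @return A `normalized_matrix`: list with dense-free sparse `values`
#'   (log of pseudocount+scaled, stored sparse when `log(pseudocount)==0`),
#'   plus metadata. Use [normalized_values] for the (cells x genes) matrix
#'   and [normalized_linear] for the pre-log scaled matrix.
#' @export
normalize_log <- function(m, mode = c("scale_to_median", "scale_to_target"),
                          log_base = 10, pseudocount = 1, target = NULL) {
  stopifnot(inherits(m, "umi_matrix"))
  mode <- match.arg(mode)
  totals <- cell_totals(m)
  if (all(totals == 0)) cs_stop("no cell with nonzero total")
  has_zero <- length(m$counts@x) < prod(dim(m$counts)) || any(m$counts@x == 0)
  if (pseudocount <= 0 && has_zero)
    cs_stop("pseudocount must be > 0 when zeros are present (log of zero)")
  tgt <- switch(mode,
                scale_to_median = median(totals),
                scale_to_target = {
                  if (is.null(target)) cs_stop("scale_to_target needs `target`")
                  target
                })
  fac <- ifelse(totals > 0, tgt / totals, 0)
  scaled <- as(Matrix::Diagonal(x = fac) %*% m$counts, "CsparseMatrix")
  values <- scaled
  values@x <- log(values@x + pseudocount, base = log_base)
  # note: zeros map to log(pseudocount); with pseudocount 1 that is 0, so the
  # sparse representation stays exact
  zero_value <- log(pseudocount, base = log_base)
  structure(list(values = values, zero_value = zero_value,
                 scaled = scaled, cell_ids = m$cell_ids,
                 gene_ids = m$gene_ids, mito_flags = m$mito_flags,
                 sample_label = m$sample_label,
                 condition_label = m$condition_label,
                 meta = list(mode = mode, target = tgt, log_base = log_base,
                             pseudocount = pseudocount,
                             dispersion_scale = "normalized-linear")),
            class = "normalized_matrix")
}

#' Log-normalized expression values (cells x genes)
#'
#' @param nm A `normalized_matrix`.
#' @param dense Return a base dense matrix (default) or the sparse form
#'   (only exact when `log(pseudocount) == 0`).
#' @return Matrix of log-normalized values.
#' @export
normalized_values <- function(nm, dense = TRUE) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (nm$zero_value == 0 && !dense) return(nm$values)
  out <- as.matrix(nm$values)
  if (nm$zero_value != 0) out[out == 0 & as.matrix(nm$scaled) == 0] <- nm$zero_value
  dimnames(out) <- list(nm$cell_ids, nm$gene_ids)
  out
}

#' Depth-scaled (pre-log) expression values
#'
#' @param nm A `normalized_matrix`.
#' @return Sparse cells x genes matrix of scaled counts.
#' @export
normalized_linear <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  out <- nm$scaled
  dimnames(out) <- list(nm$cell_ids, nm$gene_ids)
  out
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf(
    "normalized_matrix: %d cells x %d genes (%s, target %.6g, log base %s, pseudocount %g)\n",
    length(x$cell_ids), length(x$gene_ids), x$meta$mode, x$meta$target,
    format(x$meta$log_base), x$meta$pseudocount))
  invisible(x)
}
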