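#' UMI count matrix container
#'
#' A cells-by-genes sparse matrix of non-negative integer UMI counts together
#' with per-gene mitochondrial flags and per-cell sample / condition labels.
#' All pipeline stages take and return this container; counts are stored as a
#' `Matrix::dgCMatrix` so row/column sums and nonzero iteration never
#' densify.
#'
#' @param counts Cells x genes matrix (dense or sparse) of non-negative
#'   integer counts. Rows are cells.
#' @param cell_ids Unique character vector, one per row.
#' @param gene_ids Unique character vector, one per column.
#' @param mito_flags Logical per gene; defaults to `grepl(mito_prefix)`.
#' @param sample_label Character per cell (recycled if length 1).
#' @param condition_label Character per cell (recycled if length 1).
#' @param mito_prefix Gene-id prefix flagging mitochondrial genes when
#'   `mito_flags` is not given. Default `"mt-"` (mouse convention).
#' @return An object of class `umi_matrix`.
#' @export
umi_matrix <- function(counts, cell_ids = rownames(counts),
                       gene_ids = colnames(counts), mito_flags = NULL,
                       sample_label = "sample1", condition_label = "cond1",
                       mito_prefix = "mt-") {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n_cells <- nrow(counts); n_genes <- ncol(counts)
  if (is.null(cell_ids) || is.null(gene_ids))
    cs_stop("cell_ids and gene_ids are required")
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n_cells) cs_stop("cell_ids length != n_cells")
  if (length(gene_ids) != n_genes) cs_stop("gene_ids length != n_genes")
  if (anyDuplicated(cell_ids)) cs_stop("duplicate cell ids: e.g. '%s'",
                                       cell_ids[duplicated(cell_ids)][1])
  if (anyDuplicated(gene_ids)) cs_stop("duplicate gene ids: e.g. '%s'",
                                       gene_ids[duplicated(gene_ids)][1])
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    cs_stop("counts must be non-negative integers")
  if (is.null(mito_flags)) mito_flags <- startsWith(gene_ids, mito_prefix)
  if (length(mito_flags) != n_genes) cs_stop("mito_flags length != n_genes")
  recycle <- function(v) {
    if (length(v) == 1L) rep(as.character(v), n_cells) else as.character(v)
  }
  sample_label <- recycle(sample_label)
  condition_label <- recycle(condition_label)
  if (length(sample_label) != n_cells || length(condition_label) != n_cells)
    cs_stop("label vectors must have length 1 or n_cells")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 mito_flags = as.logical(mito_flags),
                 sample_label = sample_label,
                 condition_label = condition_label),
            class = "umi_matrix")
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("umi_matrix: %d cells x %d genes (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  cat(sprintf("  samples: %s\n", paste(unique(x$sample_label), collapse = ", ")))
  cat(sprintf("  conditions: %s\n",
              paste(unique(x$condition_label), collapse = ", ")))
  cat(sprintf("  mito genes: %d\n", sum(x$mito_flags)))
  invisible(x)
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

#' Subset a umi_matrix by cells and/or genes
#'
#' @param m A `umi_matrix`.
#' @param cells,genes Index vectors (logical, integer, or id character).
#' @return A `umi_matrix` with labels and flags subset consistently.
#' @export
subset_umi <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "umi_matrix"))
  ci <- if (is.null(cells)) seq_len(nrow(m$counts)) else {
    if (is.character(cells)) match(cells, m$cell_ids) else
      seq_len(nrow(m$counts))[cells]
  }
  gi <- if (is.null(genes)) seq_len(ncol(m$counts)) else {
    if (is.character(genes)) match(genes, m$gene_ids) else
      seq_len(ncol(m$counts))[genes]
  }
  if (anyNA(ci) || anyNA(gi)) cs_stop("unknown cell or gene ids in subset")
  umi_matrix(m$counts[ci, gi, drop = FALSE], m$cell_ids[ci], m$gene_ids[gi],
             m$mito_flags[gi], m$sample_label[ci], m$condition_label[ci])
}

# per-cell totals without densifying
cell_totals <- function(m) Matrix::rowSums(m$counts)

# per-cell number of detected (nonzero) genes
cells_detected_genes <- function(m) Matrix::rowSums(m$counts > 0)
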