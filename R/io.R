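#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx` (genes x cells, MatrixMarket coordinate integer),
#' `barcodes.tsv` (one barcode per line) and `features.tsv` (gene id in the
#' first column). The returned matrix is transposed to the package's
#' cells-in-rows convention; gene order follows `features.tsv`.
#'
#' @param dir Directory containing the triplet.
#' @param mito_prefix Gene-id prefix marking mitochondrial genes.
#' @param sample_label,condition_label Labels attached to every cell.
#' @return A [umi_matrix].
#' @export
read_10x_triplet <- function(dir, mito_prefix = "mt-",
                             sample_label = basename(dir),
                             condition_label = "unknown") {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) cs_stop("missing file(s): %s",
                               paste(missing, collapse = ", "))
  mm <- Matrix::readMM(paths[1])
  barcodes <- readLines(paths[2])
  feats <- read.delim(paths[3], header = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(feats[[1]])
  if (nrow(mm) != length(gene_ids))
    cs_stop("dimension mismatch: matrix has %d genes, features.tsv has %d",
            nrow(mm), length(gene_ids))
  if (ncol(mm) != length(barcodes))
    cs_stop("dimension mismatch: matrix has %d cells, barcodes.tsv has %d",
            ncol(mm), length(barcodes))
  if (anyDuplicated(barcodes))
    cs_stop("duplicate id: barcode '%s' appears more than once",
            barcodes[duplicated(barcodes)][1])
  x <- mm@x
  if (length(x) && any(x != round(x)))
    cs_stop("non-integer entries in matrix.mtx")
  umi_matrix(Matrix::t(mm), cell_ids = barcodes, gene_ids = gene_ids,
             sample_label = sample_label, condition_label = condition_label,
             mito_prefix = mito_prefix)
}

#' Write a umi_matrix as a 10x-style triplet
#'
#' Writes `matrix.mtx` in the standard genes-in-rows orientation plus
#' `barcodes.tsv` and `features.tsv`. `read_10x_triplet()` of the output is a
#' fixpoint (equal counts, ids and order).
#'
#' @param m A [umi_matrix].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_10x_triplet <- function(m, dir) {
  stopifnot(inherits(m, "umi_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir, "matrix.mtx"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = m$gene_ids, name = m$gene_ids,
                         type = "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with no
#' genes are rejected with the offending line number.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of gene ids, with a `description`
#'   attribute; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) cs_stop("GMT file '%s' contains no sets", path)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3L)
      cs_stop("malformed GMT line %d: need name, description and >=1 gene", i)
    nm[i] <- parts[1]; desc[i] <- parts[2]
    sets[[i]] <- unique(parts[-(1:2)])
  }
  if (anyDuplicated(nm)) cs_stop("duplicate set name '%s'",
                                 nm[duplicated(nm)][1])
  names(sets) <- nm
  gene_set_collection(sets, description = setNames(desc, nm))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene ids); sets must be
#'   non-empty.
#' @param description Optional named character vector of set descriptions.
#' @param category Optional named character vector of category tags.
#' @return A `gene_set_collection` (a named list with attributes).
#' @export
gene_set_collection <- function(sets, description = NULL, category = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    cs_stop("sets must be a non-empty named list")
  if (any(!vapply(sets, length, 1L)))
    cs_stop("empty gene set: '%s'",
            names(sets)[vapply(sets, length, 1L) == 0][1])
  sets <- lapply(sets, as.character)
  structure(sets, description = description, category = category,
            class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection to GMT
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  desc <- attr(gsc, "description")
  lines <- vapply(names(gsc), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, gsc[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x),
              paste(range(vapply(x, length, 1L)), collapse = "-")))
  invisible(x)
}
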