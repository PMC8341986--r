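#' Build an expression matrix with per-cell QC metadata
#'
#' Wraps a non-negative integer gene-by-cell count matrix together with the
#' per-cell statistics used in quality control: number of detected genes
#' (`n_gene`), total UMI count (`n_umi`), fraction of UMIs on mitochondrial
#' genes (`mito_frac`), fraction on ERCC spike-ins (`ercc_frac`), an optional
#' doublet score, and an optional cluster label. The QC statistics are always
#' recomputed from the counts, never trusted from the caller.
#'
#' @param counts gene x cell matrix of non-negative counts (dense or sparse;
#'   stored as a `dgCMatrix`).
#' @param gene_ids,cell_ids unique identifiers; default to dimnames.
#' @param cluster optional per-cell cluster/subtype labels (character or
#'   factor, length = number of cells).
#' @param doublet_score optional per-cell numeric doublet score.
#' @param mito_pattern,ercc_pattern regular expressions identifying
#'   mitochondrial genes and ERCC spike-ins by gene id.
#' @return An object of class `expression_matrix`: a list with elements
#'   `counts` (dgCMatrix), `gene_ids`, `cell_ids`, and `cell_meta`
#'   (data.frame with columns `cell_id`, `cluster_label`, `n_gene`, `n_umi`,
#'   `mito_frac`, `ercc_frac`, `doublet_score`).
#' @examples
#' m <- matrix(rpois(20, 2), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' em <- expression_matrix(m)
#' em$cell_meta
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              cell_ids = colnames(counts), cluster = NULL,
                              doublet_score = NULL,
                              mito_pattern = "^(mt|MT)-",
                              ercc_pattern = "^ERCC-") {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop("gene_ids/cell_ids lengths must match the matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicated gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicated cell_ids")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(gene_ids, cell_ids)

  n_umi <- Matrix::colSums(counts)
  n_gene <- Matrix::colSums(counts > 0)
  mito <- grepl(mito_pattern, gene_ids)
  ercc <- grepl(ercc_pattern, gene_ids)
  frac_of <- function(sel) {
    s <- if (any(sel)) Matrix::colSums(counts[sel, , drop = FALSE]) else 0
    ifelse(n_umi > 0, s / n_umi, 0)
  }
  if (!is.null(cluster)) {
    stopifnot(length(cluster) == ncol(counts))
    cluster <- as.character(cluster)
  }
  if (!is.null(doublet_score)) stopifnot(length(doublet_score) == ncol(counts))

  meta <- data.frame(
    cell_id = cell_ids,
    cluster_label = cluster %||% NA_character_,
    n_gene = as.integer(n_gene),
    n_umi = as.numeric(n_umi),
    mito_frac = as.numeric(frac_of(mito)),
    ercc_frac = as.numeric(frac_of(ercc)),
    doublet_score = doublet_score %||% NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = meta),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if (!all(is.na(x$cell_meta$cluster_label))) {
    k <- length(unique(x$cell_meta$cluster_label))
    cat(sprintf("  %d cluster labels\n", k))
  }
  invisible(x)
}

# subset keeping metadata consistent (QC stats are recomputed properties of
# the retained counts only through n_gene/n_umi; fractions are retained as
# computed on the full gene set, matching standard scRNA-seq practice where
# mito/ERCC fractions are frozen at ingest)
subset_expression <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  gi <- genes %||% seq_len(nrow(x$counts))
  ci <- cells %||% seq_len(ncol(x$counts))
  counts <- x$counts[gi, ci, drop = FALSE]
  meta <- x$cell_meta[ci, , drop = FALSE]
  meta$n_gene <- as.integer(Matrix::colSums(counts > 0))
  meta$n_umi <- as.numeric(Matrix::colSums(counts))
  rownames(meta) <- NULL
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_ids = colnames(counts), cell_meta = meta),
            class = "expression_matrix")
}

#' Cluster labels of an expression matrix
#' @param x an `expression_matrix`.
#' @return character vector of per-cell labels.
#' @export
cluster_labels <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  lab <- x$cell_meta$cluster_label
  if (all(is.na(lab))) stop("expression matrix carries no cluster labels")
  lab
}

#' Log-normalize a count matrix
#'
#' Library-size normalization followed by a log transform, the standard
#' single-cell normalization: each count is scaled by its cell's total UMI
#' count, multiplied by `scale`, and mapped through `log1p`, i.e.
#' `value = ln(1 + scale * count / n_umi)`. Zero counts stay exactly zero,
#' so sparsity is preserved.
#'
#' @param x an `expression_matrix`, or a plain non-negative matrix.
#' @param scale scale factor, default `1e4`.
#' @return sparse `dgCMatrix` of normalized values with the same dimnames.
#' @export
log_normalize <- function(x, scale = 1e4) {
  counts <- if (inherits(x, "expression_matrix")) x$counts else
    as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n_umi <- Matrix::colSums(counts)
  if (any(n_umi <= 0))
    stop("log_normalize: cells with zero total counts: ",
         paste(head(colnames(counts)[n_umi <= 0], 5), collapse = ", "))
  # operate on the nonzero slots directly: column of each nonzero from @p
  j <- rep.int(seq_len(ncol(counts)), diff(counts@p))
  counts@x <- log1p(scale * counts@x / n_umi[j])
  counts
}
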