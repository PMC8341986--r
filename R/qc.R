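#' Quality-control thresholds for cell filtering
#'
#' All bounds are inclusive on the keep side: a cell is retained when
#' `n_gene_min <= n_gene <= n_gene_max`, `n_umi <= n_umi_max` (if set),
#' `mito_frac <= mito_max`, `ercc_frac <= ercc_max` (if set) and
#' `doublet_score <= doublet_cutoff` (if set). Optional bounds are `NULL`.
#'
#' Two presets mirror common droplet snRNA-seq and patch-seq (full-length
#' Smart-seq) practice:
#' `qc_presets("snrna")` gives 800 <= nGene <= 6000, nUMI <= 20000,
#' mito <= 3%, doublet score <= 0.16, genes detected in >= 3 cells;
#' `qc_presets("patchseq")` gives 200 <= nGene <= 10000, mito <= 10%,
#' ERCC <= 5%, genes detected in >= 2 cells.
#'
#' @param n_gene_min,n_gene_max inclusive bounds on detected genes per cell.
#' @param n_umi_max optional inclusive upper bound on total UMIs.
#' @param mito_max inclusive upper bound on mitochondrial UMI fraction.
#' @param ercc_max optional inclusive upper bound on ERCC fraction.
#' @param min_cells_per_gene genes must be detected in at least this many
#'   cells (used by [qc_filter_genes()]).
#' @param doublet_cutoff optional inclusive upper bound on doublet score.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(n_gene_min = 800, n_gene_max = 6000,
                          n_umi_max = 20000, mito_max = 0.03,
                          ercc_max = NULL, min_cells_per_gene = 3,
                          doublet_cutoff = NULL) {
  stopifnot(n_gene_min <= n_gene_max, n_gene_min >= 0,
            mito_max >= 0, mito_max <= 1)
  if (!is.null(ercc_max)) stopifnot(ercc_max >= 0, ercc_max <= 1)
  stopifnot(min_cells_per_gene >= 1)
  structure(list(n_gene_min = n_gene_min, n_gene_max = n_gene_max,
                 n_umi_max = n_umi_max, mito_max = mito_max,
                 ercc_max = ercc_max,
                 min_cells_per_gene = min_cells_per_gene,
                 doublet_cutoff = doublet_cutoff),
            class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @param preset `"snrna"` or `"patchseq"`.
#' @export
qc_presets <- function(preset = c("snrna", "patchseq")) {
  switch(match.arg(preset),
    snrna = qc_thresholds(800, 6000, 20000, 0.03, NULL, 3, 0.16),
    patchseq = qc_thresholds(200, 10000, NULL, 0.10, 0.05, 2, NULL))
}

#' Filter cells by QC thresholds
#'
#' Drops cells violating any bound in `thresholds` and reports, for every
#' dropped cell, the first rule it failed. Rules are evaluated in a fixed
#' order: `n_gene_min`, `n_gene_max`, `n_umi_max`, `mito_max`, `ercc_max`,
#' `doublet_cutoff`. Filtering is idempotent: a second pass with the same
#' thresholds retains every cell.
#'
#' @param x an `expression_matrix`.
#' @param thresholds a `qc_thresholds` object.
#' @return list with `matrix` (filtered `expression_matrix`) and `report`
#'   (data.frame: `cell_id`, `keep`, `fail_rule` — `NA` for kept cells).
#' @export
qc_filter_cells <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(thresholds, "qc_thresholds"))
  if (ncol(x$counts) == 0L) stop("qc_filter_cells: empty matrix")
  m <- x$cell_meta
  th <- thresholds
  if (!is.null(th$doublet_cutoff) && anyNA(m$doublet_score))
    stop("qc_filter_cells: doublet_cutoff is set but doublet scores are missing")

  rules <- list(
    n_gene_min = m$n_gene < th$n_gene_min,
    n_gene_max = m$n_gene > th$n_gene_max,
    n_umi_max = if (!is.null(th$n_umi_max)) m$n_umi > th$n_umi_max,
    mito_max = m$mito_frac > th$mito_max,
    ercc_max = if (!is.null(th$ercc_max)) m$ercc_frac > th$ercc_max,
    doublet_cutoff = if (!is.null(th$doublet_cutoff))
      m$doublet_score > th$doublet_cutoff
  )
  rules <- Filter(Negate(is.null), rules)
  fail_rule <- rep(NA_character_, nrow(m))
  for (rn in rev(names(rules))) fail_rule[rules[[rn]]] <- rn
  keep <- is.na(fail_rule)
  report <- data.frame(cell_id = m$cell_id, keep = keep,
                       fail_rule = fail_rule, stringsAsFactors = FALSE)
  list(matrix = subset_expression(x, cells = which(keep)), report = report)
}

#' Filter genes by detection frequency
#'
#' Keeps genes with a nonzero count in at least `min_cells` cells; the cell
#' set is unchanged.
#'
#' @param x an `expression_matrix`.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return filtered `expression_matrix`.
#' @export
qc_filter_genes <- function(x, min_cells = 3) {
  stopifnot(inherits(x, "expression_matrix"), min_cells >= 1)
  n_cells_detected <- Matrix::rowSums(x$counts > 0)
  subset_expression(x, genes = which(n_cells_detected >= min_cells))
}
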