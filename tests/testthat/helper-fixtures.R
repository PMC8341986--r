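# Fixture builders shared across test files. All fixtures are constructed
# in code; nothing is read from disk.

# Build a sparse count matrix realizing the requested per-cell QC profile.
# Each spec row gives n_gene (detected genes incl. the mito gene when
# mito_umi > 0), n_umi (total counts) and mito_umi (counts on the single
# mitochondrial gene). Requires n_umi >= n_gene.
toy_qc_counts <- function(specs, n_genes_total = 6100) {
  stopifnot(all(specs$n_umi >= specs$n_gene))
  counts <- Matrix::Matrix(0, n_genes_total, nrow(specs), sparse = TRUE)
  rownames(counts) <- c("mt-Nd1", sprintf("g%04d", seq_len(n_genes_total - 1)))
  colnames(counts) <- sprintf("cell%d", seq_len(nrow(specs)))
  for (i in seq_len(nrow(specs))) {
    mito <- specs$mito_umi[i]
    n_plain <- specs$n_gene[i] - (mito > 0)
    stopifnot(n_plain <= n_genes_total - 1)
    v <- numeric(n_genes_total)
    v[1] <- mito
    if (n_plain > 0) {
      v[1 + seq_len(n_plain)] <- 1
      v[2] <- v[2] + (specs$n_umi[i] - mito - n_plain)
    }
    counts[, i] <- v
  }
  counts
}

# a tiny labeled normalized matrix for DEG tests: one gene, two subtypes
two_group_matrix <- function(in_vals, out_vals, gene = "g1") {
  m <- matrix(c(in_vals, out_vals), nrow = 1,
              dimnames = list(gene, sprintf("c%d", seq_len(length(in_vals) +
                                                           length(out_vals)))))
  list(mat = m, labels = rep(c("A", "B"), c(length(in_vals), length(out_vals))))
}

# small, fast simulation settings for unit tests (not the study defaults)
tiny_sim <- function(...) {
  sim_config(n_subtypes = 2, cells_per_subtype = 20, n_genes = 120,
             n_markers_per_subtype = 4, image_size = c(40, 30),
             slices_per_gene = 1, ...)
}

# pipeline config with QC bounds matched to tiny simulated matrices
tiny_pipeline_config <- function(...) {
  spaced_config(n_gene_min = 0, n_gene_max = 1e6, n_umi_max = 1e9,
                mito_max = 1, min_cells_per_gene = 1, top_n = 4, ...)
}
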