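#' Run the full spatial-classification pipeline
#'
#' Executes every stage on an expression matrix plus ISH images: cell and
#' gene QC, log normalization, one-vs-rest differential expression,
#' Jensen-Shannon specificity scoring, selection of the top reference genes
#' per subtype, ISH quantification of those genes, per-gene 0-1
#' normalization, log-mean layer specificity scores, and the ANOVA + Tukey
#' assignment rule. Any stage failure is re-raised with a stage-labeled
#' message.
#'
#' Reference genes are quantified from `ish$images`; a selected gene absent
#' from the supplied image set is dropped with a warning (the subtype is
#' scored on its remaining genes, or left unassigned if fewer than two
#' remain). An image that is declared but unreadable/missing raises an
#' error.
#'
#' @param expr an `expression_matrix` with cluster labels (and doublet
#'   scores if `config$doublet_cutoff` is set — when scores are absent the
#'   doublet rule is skipped with a message).
#' @param ish list with `images` (named list: gene -> list of `ish_image`)
#'   and `rois` (a shared `roi_set`, or named list per gene); typically
#'   `simulate_study()$ish` or the result of [read_bundle()].
#' @param config a `spaced_config`.
#' @return a `spaced_result`: list with `summary` (data.frame: subtype,
#'   n_reference_genes, the four layer scores, anova_F, anova_p,
#'   assigned_layer), `results` (per-subtype `layer_score_result`s),
#'   `score_matrix` (subtypes x layers, heatmap-ready), `reference_genes`,
#'   `deg`, `specificity`, `intensity` (per-subtype intensity matrices),
#'   `qc_report`, and `config`.
#' @export
run_spaced <- function(expr, ish, config = spaced_config()) {
  stopifnot(inherits(config, "spaced_config"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  qc <- stage("qc", {
    dc <- .na_null(config$doublet_cutoff)
    if (!is.null(dc) && all(is.na(expr$cell_meta$doublet_score))) {
      message("no doublet scores supplied; skipping doublet filter")
      dc <- NULL
    }
    th <- qc_thresholds(config$n_gene_min, config$n_gene_max,
                        .na_null(config$n_umi_max), config$mito_max,
                        .na_null(config$ercc_max),
                        config$min_cells_per_gene, dc)
    res <- qc_filter_cells(expr, th)
    res$matrix <- qc_filter_genes(res$matrix, config$min_cells_per_gene)
    res
  })
  filtered <- qc$matrix
  labels <- stage("qc", cluster_labels(filtered))

  norm <- stage("normalize", log_normalize(filtered, scale = config$norm_scale))

  deg <- stage("deg", {
    if (config$deg_method == "wilcox")
      wilcoxon_deg(norm, labels, p_adj_cutoff = config$p_adj_cutoff,
                   min_log_fc = config$min_log_fc)
    else
      roc_deg(norm, labels, power_cutoff = config$power_cutoff)
  })

  spec <- stage("specificity", {
    prof <- cluster_mean_profiles(norm, labels)
    expressed <- rowSums(prof) > 0
    specificity_scores(prof[expressed, , drop = FALSE])
  })

  refs <- stage("select-genes",
                select_reference_genes(deg, spec, n = config$top_n))

  manual <- .na_null(config$manual_threshold)
  intensities <- stage("quantify-ish", {
    lapply(refs, function(genes) {
      have <- genes %in% names(ish$images)
      if (any(!have))
        warning("no ISH images for gene(s) ",
                paste(genes[!have], collapse = ", "), "; dropped")
      genes <- genes[have]
      if (length(genes) == 0)
        return(matrix(numeric(0), 0, 4, dimnames = list(NULL, SC_LAYERS)))
      quantify_ish(ish$images[genes], ish$rois, manual = manual)
    })
  })

  results <- stage("layer-score", {
    Map(function(mat, k) score_layers(mat, subtype = k,
                                      alpha = config$alpha,
                                      epsilon = config$epsilon),
        intensities, names(intensities))
  })

  summary_df <- do.call(rbind, lapply(results, function(r) {
    sc <- as.list(r$layer_scores)
    names(sc) <- paste0("score_", gsub("/", "_", names(r$layer_scores)))
    data.frame(subtype = r$subtype, n_reference_genes = r$n_genes,
               sc, anova_F = r$anova_F, anova_p = r$anova_p,
               assigned_layer = r$assigned_layer,
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  rownames(summary_df) <- NULL
  score_matrix <- do.call(rbind, lapply(results, `[[`, "layer_scores"))
  rownames(score_matrix) <- names(results)

  structure(list(summary = summary_df, results = results,
                 score_matrix = score_matrix, reference_genes = refs,
                 deg = deg, specificity = spec, intensity = intensities,
                 qc_report = qc$report, config = config),
            class = "spaced_result")
}

#' @export
print.spaced_result <- function(x, ...) {
  cat("spaced_result\n")
  print(x$summary[, c("subtype", "n_reference_genes", "anova_p",
                      "assigned_layer")])
  invisible(x)
}
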