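#' Pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline with defaults matching
#' the published workflow: snRNA-seq QC bounds 800 <= nGene <= 6000,
#' nUMI <= 20000, mito <= 3%, doublet score <= 0.16, genes detected in at
#' least 3 cells; DEG flagging at adjusted p < 0.05 (Wilcoxon) or
#' classification power > 0.4 (ROC); top-10 reference genes per subtype;
#' assignment significance alpha = 0.05; log offset epsilon = 1e-3.
#'
#' @param n_gene_min,n_gene_max,n_umi_max,mito_max,ercc_max,doublet_cutoff,min_cells_per_gene
#'   QC bounds, see [qc_thresholds()].
#' @param norm_scale scale factor of [log_normalize()].
#' @param deg_method `"wilcox"` or `"roc"`.
#' @param p_adj_cutoff,power_cutoff,min_log_fc DEG flagging parameters.
#' @param top_n reference genes per subtype.
#' @param alpha significance level of the layer assignment.
#' @param epsilon log offset of the layer specificity score.
#' @param manual_threshold optional manual ISH threshold level.
#' @return a `spaced_config` list.
#' @export
spaced_config <- function(n_gene_min = 800, n_gene_max = 6000,
                          n_umi_max = 20000, mito_max = 0.03,
                          ercc_max = NA, doublet_cutoff = 0.16,
                          min_cells_per_gene = 3, norm_scale = 1e4,
                          deg_method = c("wilcox", "roc"),
                          p_adj_cutoff = 0.05, power_cutoff = 0.4,
                          min_log_fc = 0.25, top_n = 10, alpha = 0.05,
                          epsilon = 1e-3, manual_threshold = NA) {
  cfg <- list(n_gene_min = n_gene_min, n_gene_max = n_gene_max,
              n_umi_max = n_umi_max, mito_max = mito_max,
              ercc_max = ercc_max, doublet_cutoff = doublet_cutoff,
              min_cells_per_gene = min_cells_per_gene,
              norm_scale = norm_scale, deg_method = match.arg(deg_method),
              p_adj_cutoff = p_adj_cutoff, power_cutoff = power_cutoff,
              min_log_fc = min_log_fc, top_n = top_n, alpha = alpha,
              epsilon = epsilon, manual_threshold = manual_threshold)
  structure(cfg, class = "spaced_config")
}

.na_null <- function(x) if (length(x) == 1 && is.na(x)) NULL else x

#' Write / read a configuration as a flat key = value file
#'
#' Values are scalars; `NA` marks an unset optional bound. The round trip
#' `read_config(write_config(cfg, path))` restores the configuration
#' exactly.
#'
#' @param cfg a `spaced_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `spaced_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "spaced_config"))
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.character(v)) v else
      format(v, digits = 17, scientific = FALSE))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- setNames(lapply(kv, function(p) {
    v <- trimws(p[2])
    if (v %in% c("NA", "")) NA else
      if (grepl("^[0-9eE.+-]+$", v)) as.numeric(v) else v
  }), trimws(vapply(kv, `[`, character(1), 1)))
  known <- names(formals(spaced_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(spaced_config, vals)
}

# short content hash for provenance headers (first 10 hex digits of the md5
# of the serialized key = value text)
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  write_config(cfg, tf)
  substr(unname(tools::md5sum(tf)), 1, 10)
}

output_header <- function(cfg = NULL) {
  ver <- as.character(utils::packageVersion("spaced"))
  if (is.null(cfg)) sprintf("# spaced %s", ver)
  else sprintf("# spaced %s | config %s", ver, config_hash(cfg))
}
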