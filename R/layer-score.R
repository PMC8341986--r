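#' Normalize per-gene layer intensities to 0-1
#'
#' Each gene's four layer intensities are min-max rescaled so its weakest
#' layer becomes 0 and its strongest becomes 1; a gene with identical
#' intensity in all layers (no spatial information) becomes all zeros.
#'
#' @param intensity genes x 4 matrix of non-negative layer intensities.
#' @return genes x 4 matrix in \[0, 1\].
#' @export
normalize_gene_intensities <- function(intensity) {
  m <- as.matrix(intensity)
  if (any(m < 0)) stop("intensities must be non-negative")
  out <- t(apply(m, 1, function(r) {
    rng <- range(r)
    if (rng[1] == rng[2]) rep(0, length(r)) else (r - rng[1]) / diff(rng)
  }))
  dimnames(out) <- dimnames(m)
  out
}

#' Layer specificity scores of a subtype
#'
#' The score of a layer is the natural log of the mean normalized intensity
#' of the subtype's reference genes in that layer, offset by a small
#' `epsilon` so that layers with zero mean signal remain finite:
#' `score(layer) = ln(mean_genes(normalized) + epsilon)`. The log is
#' monotone, so the ordering of scores equals the ordering of mean
#' intensities; `epsilon` only sets the floor of the display scale.
#'
#' @param normalized genes x 4 matrix from [normalize_gene_intensities()].
#' @param epsilon offset added to the mean before the log, default 1e-3.
#' @return named numeric 4-vector of layer scores.
#' @export
layer_specificity_score <- function(normalized, epsilon = 1e-3) {
  m <- as.matrix(normalized)
  if (nrow(m) < 1) stop("need at least one gene")
  log(colMeans(m) + epsilon)
}

#' One-way ANOVA over layers with Tukey HSD post hoc
#'
#' Tests whether the normalized intensities differ between the four layers,
#' treating genes as replicates: a one-way ANOVA with layer as the factor,
#' followed by Tukey HSD over all six layer pairs. If the intensities carry
#' no variation at all (every value identical), F is 0 and all p-values 1.
#'
#' @param normalized genes x 4 matrix (>= 2 genes).
#' @return list with `anova_F`, `anova_p`, and `posthoc_p` (4 x 4 symmetric
#'   matrix of Tukey adjusted p-values, diagonal 1).
#' @export
layer_anova <- function(normalized) {
  m <- as.matrix(normalized)
  if (nrow(m) < 2) stop("layer_anova: need at least 2 genes")
  layers <- colnames(m) %||% SC_LAYERS
  df <- data.frame(value = as.vector(m),
                   layer = factor(rep(layers, each = nrow(m)), levels = layers))
  pp <- matrix(1, 4, 4, dimnames = list(layers, layers))
  if (stats::var(df$value) == 0)
    return(list(anova_F = 0, anova_p = 1, posthoc_p = pp))
  fit <- stats::aov(value ~ layer, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$layer
  for (pair in rownames(tk)) {
    ij <- strsplit(pair, "-", fixed = TRUE)[[1]]
    pp[ij[1], ij[2]] <- pp[ij[2], ij[1]] <- tk[pair, "p adj"]
  }
  list(anova_F = s[["F value"]][1], anova_p = s[["Pr(>F)"]][1],
       posthoc_p = pp)
}

#' Assign a subtype to a layer
#'
#' Assigns the top-scoring layer if and only if the overall ANOVA is
#' significant at `alpha` AND the winner's Tukey p-value against every
#' other layer is below `alpha`; otherwise the subtype is `"unassigned"`
#' (its neurons may reside in multiple laminae).
#'
#' @param scores named 4-vector of layer scores.
#' @param anova_p overall ANOVA p-value.
#' @param posthoc_p 4 x 4 Tukey p matrix from [layer_anova()].
#' @param alpha significance level, default 0.05.
#' @return the winning layer name, or `"unassigned"`.
#' @export
assign_layer <- function(scores, anova_p, posthoc_p, alpha = 0.05) {
  stopifnot(length(scores) == 4)
  layers <- names(scores) %||% SC_LAYERS
  win <- which.max(scores)
  ok <- is.finite(anova_p) && anova_p < alpha &&
    all(posthoc_p[win, -win] < alpha)
  if (ok) layers[win] else "unassigned"
}

#' Score a subtype's layer distribution from gene intensities
#'
#' Runs the scoring stage for one subtype: 0-1 normalization per gene,
#' log-mean layer specificity scores, ANOVA + Tukey HSD, and the layer
#' assignment rule. With fewer than 2 genes the significance test is not
#' defined and the subtype is returned unassigned.
#'
#' @param intensity genes x 4 matrix of background-subtracted layer
#'   intensities for the subtype's reference genes.
#' @param subtype subtype label carried through to the result.
#' @param alpha significance level for assignment.
#' @param epsilon log offset for the specificity score.
#' @return a `layer_score_result`: list with `subtype`, `normalized`,
#'   `layer_scores`, `anova_F`, `anova_p`, `posthoc_p`, `assigned_layer`,
#'   `n_genes`.
#' @export
score_layers <- function(intensity, subtype = "subtype", alpha = 0.05,
                         epsilon = 1e-3) {
  m <- as.matrix(intensity)
  if (nrow(m) == 0) {
    return(structure(list(subtype = subtype, normalized = m,
                          layer_scores = setNames(rep(NA_real_, 4), SC_LAYERS),
                          anova_F = NA_real_, anova_p = NA_real_,
                          posthoc_p = NULL, assigned_layer = "unassigned",
                          n_genes = 0L),
                     class = "layer_score_result"))
  }
  if (is.null(colnames(m))) colnames(m) <- SC_LAYERS
  norm <- normalize_gene_intensities(m)
  scores <- layer_specificity_score(norm, epsilon = epsilon)
  if (nrow(m) < 2) {
    an <- list(anova_F = NA_real_, anova_p = NA_real_, posthoc_p = NULL)
    assigned <- "unassigned"
  } else {
    an <- layer_anova(norm)
    assigned <- assign_layer(scores, an$anova_p, an$posthoc_p, alpha = alpha)
  }
  structure(list(subtype = subtype, normalized = norm, layer_scores = scores,
                 anova_F = an$anova_F, anova_p = an$anova_p,
                 posthoc_p = an$posthoc_p, assigned_layer = assigned,
                 n_genes = nrow(m)),
            class = "layer_score_result")
}

#' @export
print.layer_score_result <- function(x, ...) {
  cat(sprintf("layer_score_result: subtype %s (%d genes)\n",
              x$subtype, x$n_genes))
  print(round(x$layer_scores, 3))
  cat(sprintf("  ANOVA F = %.3g, p = %.3g -> %s\n",
              x$anova_F, x$anova_p, x$assigned_layer))
  invisible(x)
}
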