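#' Mean expression profile of each gene across subtypes
#'
#' @param norm genes x cells matrix of log-normalized expression.
#' @param labels per-cell subtype labels.
#' @return genes x subtypes matrix of mean expression (subtypes sorted).
#' @export
cluster_mean_profiles <- function(norm, labels) {
  mat <- as.matrix(norm)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(mat))
  ks <- sort(unique(labels))
  prof <- vapply(ks, function(k)
    rowMeans(mat[, labels == k, drop = FALSE]), numeric(nrow(mat)))
  dimnames(prof) <- list(rownames(mat), ks)
  prof
}

#' Jensen-Shannon subtype specificity scores
#'
#' Scores how restricted each gene's expression is to each subtype. The
#' gene's mean-expression profile across the K subtypes is normalized to a
#' probability distribution `p_g`, and for each subtype `k` the score is
#' `S_gk = 1 - sqrt(JSD(p_g, e_k))`, where `e_k` is the one-hot
#' distribution concentrated on subtype `k` and JSD is the Jensen-Shannon
#' divergence with base-2 entropies (so JSD lies in \[0, 1\] and
#' `0 * log 0 = 0`). A gene expressed exclusively in subtype `k` scores
#' exactly 1 for `k`; spreading the same mass over more subtypes strictly
#' lowers the score.
#'
#' @param mean_profiles genes x subtypes non-negative matrix, e.g. from
#'   [cluster_mean_profiles()]. Every row must have a positive sum.
#' @return data.frame (`specificity_table`) with columns `gene`, `subtype`,
#'   `specificity`, covering every gene x subtype pair.
#' @export
specificity_scores <- function(mean_profiles) {
  prof <- as.matrix(mean_profiles)
  if (any(prof < 0)) stop("mean profiles must be non-negative")
  rs <- rowSums(prof)
  if (any(rs <= 0))
    stop("specificity undefined for all-zero genes: ",
         paste(head(rownames(prof)[rs <= 0], 5), collapse = ", "))
  if (is.null(rownames(prof))) rownames(prof) <- paste0("gene", seq_len(nrow(prof)))
  if (is.null(colnames(prof))) colnames(prof) <- paste0("k", seq_len(ncol(prof)))
  S <- .jsd_specificity_matrix(prof / rs)
  data.frame(gene = rep(rownames(prof), times = ncol(prof)),
             subtype = rep(colnames(prof), each = nrow(prof)),
             specificity = as.vector(S),
             stringsAsFactors = FALSE) |>
    structure(class = c("specificity_table", "data.frame"))
}

# P: rows are probability distributions; returns genes x K matrix of
# 1 - sqrt(JSD(p, e_k)). With H(e_k) = 0, JSD = H2(m) - H2(p)/2 where the
# mixture m equals p/2 except at k, where it is (p_k + 1)/2.
.jsd_specificity_matrix <- function(P) {
  h <- function(x) ifelse(x > 0, -x * log2(x), 0)
  Hp <- rowSums(h(P))
  Hhalf <- rowSums(h(P / 2))
  S <- matrix(NA_real_, nrow(P), ncol(P), dimnames = dimnames(P))
  for (k in seq_len(ncol(P))) {
    Hm <- Hhalf - h(P[, k] / 2) + h((P[, k] + 1) / 2)
    jsd <- pmin(pmax(Hm - Hp / 2, 0), 1)
    S[, k] <- 1 - sqrt(jsd)
  }
  S
}

#' Select top specificity-ranked reference genes per subtype
#'
#' For each subtype, takes the genes flagged as DEGs for that subtype, ranks
#' them by their specificity score for that same subtype (descending; ties
#' broken by smaller adjusted p-value where available, then by gene id), and
#' returns the top `n` as the reference list used for spatial
#' classification.
#'
#' @param degs a `deg_table` from [wilcoxon_deg()] or [roc_deg()].
#' @param spec a `specificity_table` from [specificity_scores()].
#' @param n number of reference genes per subtype, default 10.
#' @return named list of character vectors (ordered gene ids), one per
#'   subtype present in `degs`. Subtypes with fewer than `n` DEGs return a
#'   shorter list with a warning; zero DEGs give an empty list.
#' @export
select_reference_genes <- function(degs, spec, n = 10) {
  stopifnot(is.data.frame(degs), is.data.frame(spec), n >= 1)
  subtypes <- sort(unique(degs$subtype))
  out <- lapply(subtypes, function(k) {
    flagged <- degs[degs$subtype == k & degs$is_deg, , drop = FALSE]
    if (nrow(flagged) == 0L) {
      warning("subtype ", k, ": no DEGs; empty reference list")
      return(character(0))
    }
    sk <- spec[spec$subtype == k, , drop = FALSE]
    idx <- match(flagged$gene, sk$gene)
    if (anyNA(idx))
      stop("specificity table does not cover all flagged genes for subtype ", k)
    flagged$specificity <- sk$specificity[idx]
    p_tie <- if ("p_adj" %in% names(flagged)) flagged$p_adj else
      rep(0, nrow(flagged))
    ord <- order(-flagged$specificity, p_tie, flagged$gene)
    sel <- flagged$gene[ord]
    if (length(sel) < n)
      warning("subtype ", k, ": only ", length(sel),
              " DEGs available for a top-", n, " list")
    head(sel, n)
  })
  names(out) <- subtypes
  out
}

#' Correlate cluster profiles between two datasets
#'
#' Computes the Pearson correlation between every pair of cluster mean
#' profiles from two datasets (e.g. patch-seq clusters against
#' high-throughput snRNA-seq subtypes), restricted to a shared gene set.
#' Profiles should be log-normalized means, or externally batch-integrated
#' values. A cluster whose restricted profile is constant has no defined
#' correlation and is reported as `NA`, never as zero.
#'
#' @param profiles_a,profiles_b genes x clusters matrices with gene
#'   rownames.
#' @param gene_set genes to restrict to; defaults to the row intersection.
#'   At least 3 genes are required.
#' @return list with `correlation` (clusters_a x clusters_b matrix in
#'   \[-1, 1\] or `NA`) and `best_match` (named character vector: for each
#'   cluster of `profiles_a`, the most correlated cluster of `profiles_b`).
#' @export
map_clusters_by_correlation <- function(profiles_a, profiles_b,
                                        gene_set = NULL) {
  a <- as.matrix(profiles_a); b <- as.matrix(profiles_b)
  if (is.null(rownames(a)) || is.null(rownames(b)))
    stop("profiles need gene rownames")
  gene_set <- gene_set %||% intersect(rownames(a), rownames(b))
  if (length(gene_set) < 3)
    stop("need at least 3 shared genes, got ", length(gene_set))
  if (!all(gene_set %in% rownames(a)) || !all(gene_set %in% rownames(b)))
    stop("gene_set contains genes absent from a profile matrix")
  a <- a[gene_set, , drop = FALSE]; b <- b[gene_set, , drop = FALSE]
  const <- c(colnames(a)[apply(a, 2, stats::sd) == 0],
             colnames(b)[apply(b, 2, stats::sd) == 0])
  if (length(const))
    warning("constant profiles, correlation undefined (NA): ",
            paste(const, collapse = ", "))
  cc <- suppressWarnings(stats::cor(a, b, method = "pearson"))
  best <- apply(cc, 1, function(r)
    if (all(is.na(r))) NA_character_ else colnames(cc)[which.max(r)])
  list(correlation = cc, best_match = best)
}
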