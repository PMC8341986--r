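#' One-vs-rest differential expression (Wilcoxon rank-sum)
#'
#' For every gene and every subtype, compares the gene's normalized
#' expression in cells of that subtype against all other cells with a
#' two-sided Wilcoxon rank-sum test. When the total number of cells is at
#' most `exact_max_n` the p-value is computed by exact enumeration over all
#' assignments of the observed (possibly tied, midranked) values to the two
#' groups; above that, the normal approximation with tie and continuity
#' correction is used. P-values are Benjamini-Hochberg adjusted per subtype
#' across all genes tested. A row is flagged as a differentially expressed
#' gene (DEG) when `p_adj < p_adj_cutoff` and `log_fc >= min_log_fc`; the
#' fold-change requirement enforces positive enrichment, i.e. markers, not
#' depleted genes.
#'
#' @param norm genes x cells matrix of log-normalized expression
#'   (see [log_normalize()]).
#' @param labels per-cell subtype labels.
#' @param p_adj_cutoff adjusted-p threshold for flagging, default 0.05.
#' @param min_log_fc minimum difference of in-group minus out-group mean
#'   log expression, default 0.25 (natural-log scale).
#' @param exact_max_n largest total group size for which the exact
#'   enumeration p-value is used, default 10.
#' @return data.frame (`deg_table`) with columns `gene`, `subtype`,
#'   `mean_in`, `mean_out`, `log_fc`, `p_raw`, `p_adj`, `method`, `is_deg`.
#'   Subtypes with fewer than 2 cells are skipped with a warning.
#' @export
wilcoxon_deg <- function(norm, labels, p_adj_cutoff = 0.05,
                         min_log_fc = 0.25, exact_max_n = 10) {
  prep <- .deg_prepare(norm, labels)
  out <- lapply(prep$subtypes, function(k) {
    grp <- prep$labels == k
    st <- .rank_sum_stats(prep$mat, prep$ranks, prep$tie_term, grp)
    n <- length(prep$labels)
    p_raw <- if (n <= exact_max_n) {
      vapply(seq_len(nrow(prep$mat)),
             function(g) wilcoxon_exact_p(prep$mat[g, grp],
                                          prep$mat[g, !grp]),
             numeric(1))
    } else {
      .rank_sum_normal_p(st$w_in, sum(grp), n - sum(grp), st$sigma2)
    }
    data.frame(gene = rownames(prep$mat), subtype = k,
               mean_in = st$mean_in, mean_out = st$mean_out,
               log_fc = st$mean_in - st$mean_out,
               p_raw = p_raw,
               p_adj = stats::p.adjust(p_raw, method = "BH"),
               method = "wilcox", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$is_deg <- res$p_adj < p_adj_cutoff & res$log_fc >= min_log_fc
  rownames(res) <- NULL
  class(res) <- c("deg_table", "data.frame")
  res
}

#' One-vs-rest differential expression (ROC classification power)
#'
#' Scores each gene x subtype by how well the gene's expression separates
#' the subtype's cells from all others: `AUC` is the Mann-Whitney
#' probability (ties counted 1/2) that an in-group cell exceeds an
#' out-group cell, and the classification power is `|2 * AUC - 1|`. A row
#' is flagged as a DEG when `power > power_cutoff` and the gene is
#' positively enriched (`log_fc >= min_log_fc`).
#'
#' @inheritParams wilcoxon_deg
#' @param power_cutoff classification-power threshold, default 0.4.
#' @param min_log_fc minimum in-minus-out mean log expression, default 0
#'   (direction only).
#' @return data.frame (`deg_table`) with columns `gene`, `subtype`,
#'   `mean_in`, `mean_out`, `log_fc`, `auc`, `power`, `method`, `is_deg`.
#' @export
roc_deg <- function(norm, labels, power_cutoff = 0.4, min_log_fc = 0) {
  prep <- .deg_prepare(norm, labels)
  out <- lapply(prep$subtypes, function(k) {
    grp <- prep$labels == k
    st <- .rank_sum_stats(prep$mat, prep$ranks, prep$tie_term, grp)
    n1 <- sum(grp); n2 <- length(prep$labels) - n1
    auc <- (st$w_in - n1 * (n1 + 1) / 2) / (n1 * n2)
    data.frame(gene = rownames(prep$mat), subtype = k,
               mean_in = st$mean_in, mean_out = st$mean_out,
               log_fc = st$mean_in - st$mean_out,
               auc = auc, power = abs(2 * auc - 1),
               method = "roc", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$is_deg <- res$power > power_cutoff & res$log_fc >= min_log_fc
  rownames(res) <- NULL
  class(res) <- c("deg_table", "data.frame")
  res
}

# shared setup: dense matrix, per-gene midranks and tie terms, usable groups
.deg_prepare <- function(norm, labels) {
  mat <- as.matrix(norm)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(mat))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("gene", seq_len(nrow(mat)))
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("skipping subtypes with fewer than 2 cells: ",
            paste(small, collapse = ", "))
  }
  subtypes <- sort(names(sizes)[sizes >= 2])
  if (length(subtypes) < 2)
    stop("differential expression needs at least 2 subtypes with >= 2 cells")
  ranks <- t(apply(mat, 1, rank))           # midranks across all cells
  tie_term <- apply(mat, 1, function(v) {   # sum(t^3 - t) over tied groups
    tt <- table(v)
    sum(tt^3 - tt)
  })
  list(mat = mat, labels = labels, subtypes = subtypes,
       ranks = ranks, tie_term = tie_term)
}

.rank_sum_stats <- function(mat, ranks, tie_term, grp) {
  n1 <- sum(grp); n <- ncol(mat); n2 <- n - n1
  w_in <- rowSums(ranks[, grp, drop = FALSE])
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  list(w_in = w_in,
       mean_in = rowMeans(mat[, grp, drop = FALSE]),
       mean_out = rowMeans(mat[, !grp, drop = FALSE]),
       sigma2 = sigma2)
}

# two-sided normal-approximation p with continuity correction
.rank_sum_normal_p <- function(w_in, n1, n2, sigma2) {
  mu <- n1 * (n1 + n2 + 1) / 2
  dev <- abs(w_in - mu)
  z <- pmax(dev - 0.5, 0) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-z)
  p[sigma2 == 0] <- 1
  pmin(p, 1)
}

#' Exact two-sided Wilcoxon rank-sum p-value by enumeration
#'
#' Enumerates all ways of assigning the pooled (midranked) observations to
#' the two groups and returns the fraction whose rank-sum deviates from its
#' expectation by at least the observed deviation. Handles ties, unlike the
#' classical exact distribution.
#'
#' @param x,y numeric observations of the two groups.
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  mu <- n1 * mean(r)
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  sets <- utils::combn(length(pooled), n1)
  stat <- abs(colSums(matrix(r[sets], nrow = n1)) - mu)
  mean(stat >= obs - 1e-9)
}
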