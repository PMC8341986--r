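# Independent oracle implementations used to cross-check the package's
# statistics. Deliberately naive: plain-loop formulas, no shared code with
# the implementation under test.

# Benjamini-Hochberg step-up, straight from the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    running_min <- min(running_min, p[o[i]] * n / i)
    adj[o[i]] <- running_min
  }
  adj
}

# Jensen-Shannon divergence (bits) between two discrete distributions,
# from the entropy definition, with 0 log 0 = 0
jsd_bits <- function(p, q) {
  H <- function(d) {
    s <- 0
    for (x in d) if (x > 0) s <- s - x * log2(x)
    s
  }
  m <- (p + q) / 2
  H(m) - (H(p) + H(q)) / 2
}

jsd_specificity_oracle <- function(profile, k) {
  p <- profile / sum(profile)
  e <- rep(0, length(p)); e[k] <- 1
  1 - sqrt(jsd_bits(p, e))
}

# one-way ANOVA F and p from the between/within mean-square definition;
# groups: list of numeric vectors
anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE),
       mse = ssw / dfw, dfw = dfw)
}

# Tukey HSD adjusted p for one pair in a balanced one-way layout
tukey_oracle <- function(groups, i, j) {
  a <- anova_oracle(groups)
  n <- length(groups[[i]])
  q <- abs(mean(groups[[i]]) - mean(groups[[j]])) / sqrt(a$mse / n)
  stats::ptukey(q, nmeans = length(groups), df = a$dfw, lower.tail = FALSE)
}

# exact two-sided rank-sum p by enumerating every group assignment
wilcoxon_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  mu <- n1 * mean(r)
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0; total <- 0
  for (idx in asplit(utils::combn(length(pooled), n1), 2)) {
    total <- total + 1
    if (abs(sum(r[idx]) - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / total
}
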