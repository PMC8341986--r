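test_that("exact Wilcoxon p matches hand-enumerated cases", {
  # perfect separation of 3 vs 3: only 2 of the C(6,3)=20 assignments are
  # as extreme, so p = 0.1
  expect_equal(wilcoxon_exact_p(c(4, 5, 6), c(1, 2, 3)), 0.1)
  # identical groups: no rank separation
  expect_equal(wilcoxon_exact_p(c(1, 2), c(1, 2)), 1)
})

test_that("exact enumeration agrees with the classical exact distribution", {
  # tie-free data: enumeration must reproduce wilcox.test's exact p
  set.seed(101)
  for (sizes in list(c(2, 3), c(3, 3), c(4, 4), c(3, 5), c(2, 6))) {
    x <- sample(100, sizes[1]); y <- sample(200, sizes[2]) + 0.5
    expect_equal(wilcoxon_exact_p(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12,
                 info = paste(sizes, collapse = "v"))
  }
})

test_that("wilcoxon_deg uses the exact path on small groups", {
  tg <- two_group_matrix(c(4, 5, 6), c(1, 2, 3))
  tab <- wilcoxon_deg(tg$mat, tg$labels, min_log_fc = 0)
  a <- tab[tab$subtype == "A", ]
  expect_equal(a$p_raw, 0.1)
  expect_equal(a$log_fc, mean(c(4, 5, 6)) - mean(c(1, 2, 3)))
  expect_equal(a$p_adj, 0.1)  # single test
})

test_that("normal approximation tracks wilcox.test on larger tied data", {
  set.seed(7)
  n <- 30
  labels <- rep(c("A", "B"), each = n)
  vals <- matrix(sample(0:5, 4 * 2 * n, replace = TRUE), nrow = 4,
                 dimnames = list(paste0("g", 1:4), NULL))
  vals[1, labels == "A"] <- vals[1, labels == "A"] + 3  # one clear marker
  tab <- wilcoxon_deg(vals, labels, min_log_fc = 0)
  for (g in rownames(vals)) {
    ref <- suppressWarnings(
      stats::wilcox.test(vals[g, labels == "A"], vals[g, labels == "B"],
                         correct = TRUE))$p.value
    expect_equal(tab$p_raw[tab$gene == g & tab$subtype == "A"], ref,
                 tolerance = 1e-10, info = g)
  }
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(13)
  sim <- simulate_expression(tiny_sim(seed = 13))
  norm <- log_normalize(qc_filter_genes(sim$matrix, 1))
  tab <- wilcoxon_deg(norm, sim$truth$labels)
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))
  for (k in unique(tab$subtype)) {
    sub <- tab[tab$subtype == k, ]
    ord <- order(sub$p_raw)
    expect_true(all(diff(sub$p_adj[ord]) >= -1e-15))
  }
})

test_that("DEG flagging requires positive enrichment", {
  set.seed(29)
  # a strongly depleted gene: significant but negative log_fc
  tg <- two_group_matrix(rep(c(0, 0.1), 10), rep(c(3, 4), 10))
  tab <- wilcoxon_deg(tg$mat, tg$labels)
  a <- tab[tab$subtype == "A", ]
  expect_lt(a$p_adj, 0.05)
  expect_false(a$is_deg)
  b <- tab[tab$subtype == "B", ]
  expect_true(b$is_deg)
})

test_that("subtypes with fewer than 2 cells are skipped with a warning", {
  m <- matrix(1:10, nrow = 2, dimnames = list(c("g1", "g2"), NULL))
  expect_warning(tab <- wilcoxon_deg(m, c("A", "A", "B", "B", "C")),
                 "fewer than 2 cells")
  expect_setequal(unique(tab$subtype), c("A", "B"))
  m4 <- m[, 1:4]
  expect_error(suppressWarnings(wilcoxon_deg(m4, c("A", "A", "A", "C"))),
               "at least 2 subtypes")
})

test_that("ROC power is |2 AUC - 1| with ties counted half", {
  tg <- two_group_matrix(c(1, 3), c(2, 4))
  tab <- roc_deg(tg$mat, tg$labels)
  a <- tab[tab$subtype == "A", ]
  expect_equal(a$auc, 0.25)
  expect_equal(a$power, 0.5)
  expect_false(a$is_deg)  # depleted, not enriched

  sep <- two_group_matrix(c(10, 11, 12), c(1, 2, 3))
  s <- roc_deg(sep$mat, sep$labels)
  expect_equal(s$auc[s$subtype == "A"], 1)
  expect_equal(s$power[s$subtype == "A"], 1)
  expect_true(s$is_deg[s$subtype == "A"])

  same <- two_group_matrix(c(5, 5, 5), c(5, 5, 5))
  eq <- roc_deg(same$mat, same$labels)
  expect_equal(eq$auc, c(0.5, 0.5))
  expect_equal(eq$power, c(0, 0))
})
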