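test_that("per-gene intensities are min-max normalized to [0, 1]", {
  m <- rbind(g1 = c(10, 35, 5, 20), g2 = c(3, 3, 3, 3))
  norm <- normalize_gene_intensities(m)
  expect_equal(unname(norm["g1", ]), c(1 / 6, 1, 0, 0.5), tolerance = 1e-12)
  expect_equal(unname(norm["g2", ]), rep(0, 4))  # degenerate rule
  # any non-degenerate row attains exactly one 0 and one 1 when extremes
  # are unique
  expect_equal(sum(norm["g1", ] == 0), 1)
  expect_equal(sum(norm["g1", ] == 1), 1)
})

test_that("layer score is the log of the mean normalized intensity plus epsilon", {
  norm <- rbind(c(0.9, 0.2, 0.1, 0.05), c(0.9, 0.2, 0.1, 0.05))
  colnames(norm) <- c("SuG", "Op", "InG/InWh", "DpG")
  sc <- layer_specificity_score(norm, epsilon = 1e-3)
  expect_equal(unname(sc), log(c(0.901, 0.201, 0.101, 0.051)))
  # equal means give equal scores; permutation is equivariant
  eq <- layer_specificity_score(rbind(rep(0.3, 4)))
  expect_true(all(eq == eq[1]))
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(layer_specificity_score(norm[, perm])), unname(sc[perm]))
})

test_that("layer ANOVA matches the closed-form mean-square ratio", {
  # genes as replicates: layer groups {1,2}, {5,6}, {1,2}, {1,2}
  m <- rbind(c(1, 5, 1, 1), c(2, 6, 2, 2))
  colnames(m) <- c("SuG", "Op", "InG/InWh", "DpG")
  res <- layer_anova(m)
  oracle <- anova_oracle(list(c(1, 2), c(5, 6), c(1, 2), c(1, 2)))
  expect_equal(res$anova_F, oracle$F, tolerance = 1e-10)
  expect_equal(res$anova_p, oracle$p, tolerance = 1e-10)
  expect_equal(oracle$F, 16)  # by hand: (24/3) / (2/4)
})

test_that("Tukey post hoc p-values match the studentized-range oracle", {
  set.seed(55)
  m <- matrix(stats::rnorm(24, mean = rep(c(0, 2, 0.5, 1), each = 6)), 6,
              dimnames = list(NULL, c("SuG", "Op", "InG/InWh", "DpG")))
  res <- layer_anova(m)
  groups <- lapply(seq_len(4), function(j) m[, j])
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(res$posthoc_p[i, j], tukey_oracle(groups, i, j),
                 tolerance = 1e-10)
  }
  expect_equal(diag(res$posthoc_p), setNames(rep(1, 4), colnames(m)))
  expect_equal(res$posthoc_p, t(res$posthoc_p))
})

test_that("degenerate inputs give F = 0, p = 1", {
  m <- rbind(rep(0, 4), rep(0, 4))
  colnames(m) <- c("SuG", "Op", "InG/InWh", "DpG")
  res <- layer_anova(m)
  expect_equal(res$anova_F, 0)
  expect_equal(res$anova_p, 1)
  expect_true(all(res$posthoc_p == 1))
  expect_error(layer_anova(m[1, , drop = FALSE]), "at least 2 genes")
})

test_that("assignment requires overall and pairwise significance", {
  scores <- c(SuG = -0.1, Op = -3, `InG/InWh` = -3, DpG = -4)
  strong <- matrix(1e-6, 4, 4); diag(strong) <- 1
  dimnames(strong) <- list(names(scores), names(scores))
  expect_equal(assign_layer(scores, 1e-6, strong), "SuG")
  # insignificant ANOVA: unassigned regardless of scores
  expect_equal(assign_layer(scores, 0.5, strong), "unassigned")
  # winner not separated from runner-up
  weak <- strong
  weak["SuG", "Op"] <- weak["Op", "SuG"] <- 0.2
  expect_equal(assign_layer(scores, 1e-6, weak), "unassigned")
  # an assigned layer is always the top scorer
  expect_equal(assign_layer(scores, 1e-6, strong, alpha = 0.05), "SuG")
})

test_that("score_layers is invariant to gene order and duplication", {
  set.seed(77)
  m <- matrix(stats::runif(40, 0, 50), 10,
              dimnames = list(paste0("g", 1:10),
                              c("SuG", "Op", "InG/InWh", "DpG")))
  base <- score_layers(m)
  shuffled <- score_layers(m[sample(10), ])
  expect_equal(shuffled$layer_scores, base$layer_scores)
  doubled <- score_layers(rbind(m, m))
  expect_equal(doubled$layer_scores, base$layer_scores)
  expect_equal(doubled$assigned_layer, base$assigned_layer)
})

test_that("score_layers handles starved gene lists without testing", {
  empty <- score_layers(matrix(numeric(0), 0, 4))
  expect_equal(empty$assigned_layer, "unassigned")
  expect_equal(empty$n_genes, 0L)
  single <- score_layers(matrix(c(5, 1, 0, 0), 1,
                                dimnames = list("g", NULL)))
  expect_equal(single$assigned_layer, "unassigned")
  expect_true(is.na(single$anova_p))
})
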