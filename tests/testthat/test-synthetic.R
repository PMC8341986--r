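test_that("simulation is deterministic under a fixed seed", {
  cf <- tiny_sim(seed = 99)
  a <- simulate_expression(cf)
  b <- simulate_expression(cf)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth, b$truth)
  ia <- simulate_ish_image(cf, "Op")
  ib <- simulate_ish_image(cf, "Op")
  expect_identical(ia$image$pixels, ib$image$pixels)
  sa <- simulate_study(cf)
  sb <- simulate_study(cf)
  expect_identical(sa$ish$images[[names(sa$ish$images)[1]]],
                   sb$ish$images[[names(sb$ish$images)[1]]])
  expect_identical(sa$truth, sb$truth)
})

test_that("simulated matrices satisfy the expression invariants", {
  sim <- simulate_expression(tiny_sim(seed = 4))
  em <- sim$matrix
  expect_true(all(em$counts@x >= 0))
  expect_equal(em$cell_meta$n_umi, unname(Matrix::colSums(em$counts)))
  expect_equal(em$cell_meta$n_gene,
               unname(as.integer(Matrix::colSums(em$counts > 0))))
  expect_false(anyDuplicated(em$gene_ids) > 0)
  expect_true(all(em$cell_meta$mito_frac >= 0 & em$cell_meta$mito_frac <= 1))
  # planted markers are disjoint from mito/ERCC tag genes
  mk <- unlist(sim$truth$markers)
  expect_false(any(grepl("^(mt|ERCC)-", mk)))
})

test_that("planted markers carry real enrichment in their own subtype", {
  sim <- simulate_expression(tiny_sim(seed = 8, marker_fold = 8))
  norm <- log_normalize(sim$matrix)
  labels <- sim$truth$labels
  for (k in names(sim$truth$markers)) {
    mk <- sim$truth$markers[[k]]
    m_in <- rowMeans(as.matrix(norm[mk, labels == k, drop = FALSE]))
    m_out <- rowMeans(as.matrix(norm[mk, labels != k, drop = FALSE]))
    expect_true(all(m_in > m_out))
  }
})

test_that("a fold of 1 simulates the null with essentially no flagged DEGs", {
  clean <- 0
  for (s in 1:5) {
    sim <- simulate_expression(tiny_sim(seed = 300 + s, marker_fold = 1))
    norm <- log_normalize(qc_filter_genes(sim$matrix, 3))
    tab <- wilcoxon_deg(norm, sim$truth$labels)
    if (sum(tab$is_deg) == 0) clean <- clean + 1
  }
  expect_gte(clean, 4)
})

test_that("simulated image signal density matches the Bernoulli expectation", {
  cf <- sim_config(noise_sd = 0, signal_density_in = 0.4,
                   signal_density_out = 0.02, image_size = c(100, 100),
                   seed = 17)
  sim <- simulate_ish_image(cf, true_layer = "Op")
  band <- sim$rois$layers$Op
  af <- 100 * sum(sim$truth_mask & band) / sum(band)
  expect_equal(af, 40, tolerance = 0.1)  # 2000-pixel band, ~3 sd slack
  out <- 100 * sum(sim$truth_mask & sim$rois$background) /
    sum(sim$rois$background)
  expect_lt(out, 5)
})

test_that("equal in/out densities remove the spatial signal", {
  cf <- sim_config(signal_density_in = 0.05, signal_density_out = 0.05,
                   image_size = c(60, 40), seed = 23)
  sim <- simulate_ish_image(cf, true_layer = "SuG")
  af <- vapply(sim$rois$layers, function(b)
    100 * sum(sim$truth_mask & b) / sum(b), numeric(1))
  expect_lt(diff(range(af)), 5)
})

test_that("thresholding recovers the planted signal mask accurately", {
  cf <- sim_config(image_size = c(100, 100), seed = 31)
  sim <- simulate_ish_image(cf, true_layer = "InG/InWh")
  mask <- auto_threshold(to_8bit(sim$image))
  accuracy <- mean(mask == sim$truth_mask)
  expect_gte(accuracy, 0.95)
})

test_that("generated ROI bands satisfy the ROI invariants by construction", {
  cf <- sim_config(image_size = c(50, 44),
                   layer_band_fractions = c(0.3, 0.2, 0.2, 0.1))
  sim <- simulate_ish_image(cf, "DpG")
  expect_s3_class(sim$rois, "roi_set")  # constructor enforces invariants
  total <- Reduce(`+`, c(sim$rois$layers, list(sim$rois$background)))
  expect_lte(max(total), 1)
  expect_error(sim_config(layer_band_fractions = c(0.5, 0.3, 0.2, 0.1)),
               "sum to at most 1")
})
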