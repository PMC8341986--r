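make_rois <- function(nr = 10, nc = 10) {
  # two-row bands for the four layers, last two rows background
  masks <- lapply(0:3, function(i) {
    m <- matrix(FALSE, nr, nc); m[(2 * i + 1):(2 * i + 2), ] <- TRUE; m
  })
  names(masks) <- c("SuG", "Op", "InG/InWh", "DpG")
  bg <- matrix(FALSE, nr, nc); bg[(nr - 1):nr, ] <- TRUE
  roi_set(masks, bg)
}

test_that("to_8bit rescales linearly with round-half-up", {
  img <- ish_image(matrix(c(0, 0.5, 1, 0.25), 2))
  out <- to_8bit(img)
  expect_equal(sort(as.vector(out$pixels)), c(0, 64, 128, 255))
  # constant image maps to zeros
  expect_true(all(to_8bit(matrix(7, 3, 3))$pixels == 0))
  # already 8-bit full-range image is unchanged
  full <- matrix(c(0, 255, 100, 30), 2)
  expect_equal(to_8bit(full)$pixels, full)
})

test_that("to_8bit is monotone in pixel value", {
  set.seed(5)
  px <- matrix(stats::runif(100, 0, 1000), 10)
  out <- to_8bit(px)$pixels
  expect_true(all(diff(out[order(px)]) >= 0))
})

test_that("IsoData threshold separates a two-spike histogram between its modes", {
  img <- ish_image(matrix(c(rep(10, 50), rep(200, 50)), 10, 10))
  mask <- auto_threshold(img)
  expect_equal(sum(mask), 50)
  expect_gt(attr(mask, "level"), 10)
  expect_lte(attr(mask, "level"), 200)
  # intermeans fixed point of the two-spike histogram is (10 + 200) / 2
  expect_equal(attr(mask, "level"), 106)
})

test_that("manual threshold overrides and constant images give no signal", {
  img <- ish_image(matrix(c(rep(10, 50), rep(200, 50)), 10, 10))
  expect_equal(sum(auto_threshold(img, manual = 0)), 100)
  expect_equal(sum(auto_threshold(img, manual = 201)), 0)
  expect_warning(m <- auto_threshold(ish_image(matrix(42, 4, 4))),
                 "constant")
  expect_equal(sum(m), 0)
})

test_that("area fraction counts highlighted pixels within the ROI", {
  roi <- matrix(TRUE, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:5, 1:5] <- TRUE  # 25 pixels
  expect_equal(area_fraction(mask, roi), 25)
  expect_equal(area_fraction(matrix(FALSE, 10, 10), roi), 0)
  expect_equal(area_fraction(roi, roi), 100)
  expect_error(area_fraction(mask, matrix(FALSE, 10, 10)), "empty ROI")
})

test_that("area fraction is pixel-count-weighted under disjoint ROI union", {
  set.seed(21)
  for (i in 1:20) {
    mask <- matrix(stats::runif(400) < 0.3, 20)
    sel <- sample(400, 200)
    a <- matrix(FALSE, 20, 20); a[sel[1:80]] <- TRUE
    b <- matrix(FALSE, 20, 20); b[sel[81:200]] <- TRUE
    af_union <- area_fraction(mask, a | b)
    expected <- (area_fraction(mask, a) * sum(a) +
                 area_fraction(mask, b) * sum(b)) / (sum(a) + sum(b))
    expect_equal(af_union, expected, tolerance = 1e-12)
  }
})

test_that("signal intensity subtracts the background area fraction and clips", {
  rois <- make_rois()
  px <- matrix(10, 10, 10)
  px[1:2, ] <- 200            # SuG fully signal
  px[3:4, 1:4] <- 200         # Op: 40% signal
  px[9, 1] <- 200             # background: 1/20 = 5% signal
  si <- signal_intensity(ish_image(px), rois)
  expect_equal(unname(si), c(95, 35, 0, 0))
  expect_named(si, c("SuG", "Op", "InG/InWh", "DpG"))
  # zero-signal image: constant, empty mask, all intensities 0
  expect_equal(unname(signal_intensity(ish_image(matrix(9, 10, 10)), rois)),
               rep(0, 4))
})

test_that("quantification is invariant to a constant pixel offset", {
  set.seed(33)
  rois <- make_rois()
  px <- matrix(stats::runif(100, 0, 200), 10)
  expect_equal(signal_intensity(ish_image(px), rois),
               signal_intensity(ish_image(px + 37), rois))
})

test_that("quantify_gene averages slices and ignores their order", {
  rois <- make_rois()
  img1 <- ish_image(matrix(10, 10, 10), slice_id = "s1")
  img1$pixels[1:2, ] <- 200                      # SuG AF 100, bg 0
  img2 <- ish_image(matrix(10, 10, 10), slice_id = "s2")
  img2$pixels[1:2, 1:4] <- 200                   # SuG AF 40, bg 0
  q12 <- quantify_gene(list(img1, img2), rois = rois)
  expect_equal(as.numeric(q12), c(70, 0, 0, 0))
  expect_equal(attr(q12, "n_slices"), 2)
  q21 <- quantify_gene(list(img2, img1), rois = rois)
  expect_equal(as.numeric(q21), as.numeric(q12))
  # single slice equals signal_intensity
  expect_equal(as.numeric(quantify_gene(list(img1), rois = rois)),
               as.numeric(signal_intensity(img1, rois)))
  expect_error(quantify_gene(list(), rois = rois), "no slices")
})

test_that("roi_set validates geometry", {
  rois <- make_rois()
  bad <- rois$layers
  bad$Op <- bad$SuG  # overlap
  expect_error(roi_set(bad, rois$background), "disjoint")
  empty <- rois$layers
  empty$DpG <- matrix(FALSE, 10, 10)
  expect_error(roi_set(empty, rois$background), "non-empty")
  expect_error(roi_set(rois$layers[c(1, 2, 3, 3)], rois$background), "named")
})
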