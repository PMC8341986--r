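#' Construct an ISH image
#'
#' A grayscale in situ hybridization slice: a 2-D grid of finite,
#' non-negative pixel values, tagged with the gene and slice identifiers.
#'
#' @param pixels numeric matrix (rows x cols), at least 2 x 2, finite.
#' @param gene gene id the slice stains for.
#' @param slice_id slice identifier.
#' @return an `ish_image` object.
#' @export
ish_image <- function(pixels, gene = "unknown", slice_id = "slice1") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2 || ncol(pixels) < 2)
    stop("ish_image: need at least a 2x2 pixel grid")
  if (!all(is.finite(pixels))) stop("ish_image: pixels must be finite")
  if (any(pixels < 0)) stop("ish_image: pixels must be non-negative")
  structure(list(pixels = pixels, gene = as.character(gene),
                 slice_id = as.character(slice_id)),
            class = "ish_image")
}

.pixels <- function(img) {
  if (inherits(img, "ish_image")) img$pixels else as.matrix(img)
}

#' @export
print.ish_image <- function(x, ...) {
  cat(sprintf("ish_image %s/%s: %d x %d, range [%g, %g]\n", x$gene,
              x$slice_id, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct an ROI set for the four laminae plus background
#'
#' Boolean masks, congruent with the image grid, for the four layers of the
#' superior colliculus — SuG, Op, InG/InWh, DpG — plus one background
#' region (by convention the region with the weakest signal). Layer masks
#' must be pairwise disjoint, the background disjoint from all layers, and
#' every mask non-empty.
#'
#' @param layers named list of 4 logical matrices, names
#'   `c("SuG", "Op", "InG/InWh", "DpG")` (any order; stored canonically).
#' @param background logical matrix.
#' @return an `roi_set` object.
#' @export
roi_set <- function(layers, background) {
  if (!setequal(names(layers), SC_LAYERS))
    stop("roi_set: layer masks must be named ",
         paste(SC_LAYERS, collapse = ", "))
  layers <- lapply(layers[SC_LAYERS], function(m) {
    m <- as.matrix(m); storage.mode(m) <- "logical"; m
  })
  background <- as.matrix(background); storage.mode(background) <- "logical"
  dims <- unique(lapply(c(layers, list(background)), dim))
  if (length(dims) != 1) stop("roi_set: masks are not congruent")
  all_masks <- c(layers, list(background = background))
  if (any(!vapply(all_masks, any, logical(1))))
    stop("roi_set: every mask must be non-empty")
  overlap <- Reduce(`+`, c(layers, list(background)))
  if (any(overlap > 1))
    stop("roi_set: layer/background masks must be pairwise disjoint")
  structure(list(layers = layers, background = background),
            class = "roi_set")
}

#' Convert an image to 8-bit
#'
#' Linearly rescales pixel values so the minimum maps to 0 and the maximum
#' to 255, rounding half up to integers. A constant image maps to all
#' zeros. The rescale makes downstream quantification invariant to adding a
#' constant offset to all pixels.
#'
#' @param img an `ish_image` or numeric matrix.
#' @return an `ish_image` with integer pixels in \[0, 255\].
#' @export
to_8bit <- function(img) {
  px <- .pixels(img)
  rng <- range(px)
  out <- if (rng[1] == rng[2]) array(0, dim(px)) else
    floor((px - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)
  if (inherits(img, "ish_image"))
    ish_image(out, img$gene, img$slice_id)
  else ish_image(out)
}

#' Automatic signal threshold (IsoData intermeans)
#'
#' Computes a signal mask for an 8-bit image. The IsoData method iterates
#' the intermeans rule on the 256-bin histogram: starting from the image
#' mean, the threshold is repeatedly replaced by the average of the mean
#' pixel value below (inclusive) and above it, until it stabilizes; signal
#' pixels are those with value `>= level`, where `level` is one more than
#' the converged threshold. A `manual` level overrides the automatic one
#' (`manual = 0` marks every pixel as signal). A constant image yields an
#' empty mask with a warning.
#'
#' @param img an `ish_image` with integer pixels in \[0, 255\]
#'   (see [to_8bit()]).
#' @param method currently only `"isodata"`.
#' @param manual optional manual threshold level in \[0, 255\].
#' @return logical matrix marking signal pixels; the chosen level is
#'   attached as attribute `"level"`.
#' @export
auto_threshold <- function(img, method = "isodata", manual = NULL) {
  method <- match.arg(method, "isodata")
  px <- .pixels(img)
  if (any(px != floor(px)) || min(px) < 0 || max(px) > 255)
    stop("auto_threshold expects an 8-bit image; run to_8bit() first")
  if (!is.null(manual)) {
    stopifnot(manual >= 0, manual <= 255)
    return(structure(px >= manual, dim = dim(px), level = manual))
  }
  if (min(px) == max(px)) {
    warning("constant image: no signal")
    return(structure(array(FALSE, dim(px)), level = NA_real_))
  }
  h <- tabulate(as.vector(px) + 1L, nbins = 256L)  # h[v+1] = count of value v
  v <- 0:255
  t <- floor(sum(h * v) / sum(h))
  repeat {
    lo <- v <= t
    mb <- sum(h[lo] * v[lo]) / sum(h[lo])
    ma <- sum(h[!lo] * v[!lo]) / sum(h[!lo])
    t_new <- floor((mb + ma) / 2)
    if (!is.finite(t_new) || t_new == t) break
    t <- t_new
  }
  level <- t + 1
  structure(px >= level, dim = dim(px), level = level)
}

#' Area fraction of signal inside an ROI
#'
#' Percentage of ROI pixels that are signal:
#' `100 * |signal AND roi| / |roi|`.
#'
#' @param mask logical signal mask.
#' @param roi logical ROI mask, congruent with `mask`, non-empty.
#' @return percentage in \[0, 100\].
#' @export
area_fraction <- function(mask, roi) {
  mask <- as.matrix(mask); roi <- as.matrix(roi)
  if (!identical(dim(mask), dim(roi)))
    stop("area_fraction: mask and roi are not congruent")
  n_roi <- sum(roi)
  if (n_roi == 0) stop("area_fraction: empty ROI")
  100 * sum(mask & roi) / n_roi
}

#' Background-subtracted layer signal intensities of one slice
#'
#' Converts the slice to 8-bit, thresholds it, computes the signal area
#' fraction in each of the four layer ROIs and in the background ROI, and
#' returns the background-subtracted fractions, clipped at zero (a layer
#' dimmer than the background carries no signal, only noise).
#'
#' @param img an `ish_image`.
#' @param rois an `roi_set`.
#' @param manual optional manual threshold level (see [auto_threshold()]).
#' @return named numeric 4-vector of layer intensities in \[0, 100\].
#' @export
signal_intensity <- function(img, rois, manual = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  img8 <- to_8bit(img)
  if (!identical(dim(img8$pixels), dim(rois$background)))
    stop("signal_intensity: image and ROI grids are not congruent")
  mask <- suppressWarnings(auto_threshold(img8, manual = manual))
  af <- vapply(rois$layers, area_fraction, numeric(1), mask = mask)
  bg <- area_fraction(mask, rois$background)
  pmax(af - bg, 0)
}

#' Quantify one gene over its slices
#'
#' Averages the background-subtracted layer intensities over all available
#' slices of a gene (arithmetic mean per layer); the slice count is
#' recorded as attribute `"n_slices"`. The result is invariant to slice
#' order.
#'
#' @param slices list where each element is a list with components `image`
#'   (an `ish_image`) and `rois` (an `roi_set`); alternatively a list of
#'   `ish_image`s with a single shared `rois`.
#' @param rois optional shared `roi_set` when `slices` is a plain image
#'   list.
#' @param manual optional manual threshold level.
#' @return named numeric 4-vector of mean layer intensities.
#' @export
quantify_gene <- function(slices, rois = NULL, manual = NULL) {
  if (length(slices) == 0) stop("quantify_gene: no slices supplied")
  per_slice <- vapply(slices, function(s) {
    if (inherits(s, "ish_image")) {
      if (is.null(rois)) stop("quantify_gene: shared rois required")
      signal_intensity(s, rois, manual = manual)
    } else {
      signal_intensity(s$image, s$rois, manual = manual)
    }
  }, numeric(4))
  structure(rowMeans(per_slice), n_slices = length(slices))
}

#' Quantify a panel of genes
#'
#' @param images named list: gene id -> list of `ish_image` slices.
#' @param rois a shared `roi_set`, or a named list (gene id -> `roi_set`
#'   or list of per-slice `roi_set`s).
#' @param manual optional manual threshold level.
#' @return genes x 4 matrix of mean layer intensities (an
#'   `ish_quantification`), with per-gene slice counts in attribute
#'   `"n_slices"`.
#' @export
quantify_ish <- function(images, rois, manual = NULL) {
  stopifnot(length(images) > 0, !is.null(names(images)))
  res <- t(vapply(names(images), function(g) {
    slices <- images[[g]]
    if (length(slices) == 0)
      stop("quantify-ish: missing input: gene ", g, " has no slices")
    r <- if (inherits(rois, "roi_set")) rois else rois[[g]]
    if (is.null(r)) stop("quantify-ish: missing ROI set for gene ", g)
    if (inherits(r, "roi_set")) quantify_gene(slices, rois = r, manual = manual)
    else quantify_gene(Map(function(im, rs) list(image = im, rois = rs),
                           slices, r), manual = manual)
  }, numeric(4)))
  colnames(res) <- SC_LAYERS
  structure(res, n_slices = vapply(images, length, integer(1)),
            class = c("ish_quantification", class(res)))
}

#' Propose a background region of minimal mean intensity
#'
#' Convenience helper (an extension to the published manual workflow, where
#' the weakest-signal background region is chosen by eye): slides a
#' rectangular window over the image and returns the position with the
#' lowest mean pixel value as a logical mask.
#'
#' @param img an `ish_image`.
#' @param window `c(rows, cols)` size of the candidate region.
#' @param stride step between candidate positions, default half the window.
#' @return logical mask of the selected region.
#' @export
propose_background <- function(img, window = c(16, 16),
                               stride = pmax(1L, window %/% 2L)) {
  px <- .pixels(img)
  stopifnot(all(window <= dim(px)))
  rs <- seq(1, nrow(px) - window[1] + 1, by = stride[1])
  cs <- seq(1, ncol(px) - window[2] + 1, by = stride[2])
  best <- NULL; best_mean <- Inf
  for (i in rs) for (j in cs) {
    m <- mean(px[i:(i + window[1] - 1), j:(j + window[2] - 1)])
    if (m < best_mean) { best_mean <- m; best <- c(i, j) }
  }
  mask <- array(FALSE, dim(px))
  mask[best[1]:(best[1] + window[1] - 1),
       best[2]:(best[2] + window[2] - 1)] <- TRUE
  mask
}
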