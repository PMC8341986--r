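#' Read a count matrix from disk
#'
#' Supports two layouts: a Cell Ranger-style triplet directory containing
#' `matrix.mtx` (Matrix Market), `genes.tsv` and `barcodes.tsv` (one id
#' per line; an optional `cell_meta.tsv` is merged in), or a dense CSV/TSV
#' file with gene rows, a header of cell ids, and the gene id in the first
#' column. Gzipped variants (`.gz`) are read transparently.
#'
#' @param path directory (triplet layout) or file (dense, `.mtx`).
#' @param cell_meta optional path to a cell metadata TSV with a `cell_id`
#'   column and any of `cluster_label`, `doublet_score`.
#' @return an `expression_matrix`.
#' @export
read_count_matrix <- function(path, cell_meta = NULL) {
  if (dir.exists(path)) {
    find1 <- function(base) {
      for (f in c(file.path(path, base), file.path(path, paste0(base, ".gz"))))
        if (file.exists(f)) return(f)
      stop("missing file in triplet directory: ", base)
    }
    mtx <- find1("matrix.mtx")
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("malformed Matrix Market file ",
                                           mtx, ": ", conditionMessage(e)))
    genes <- .read_id_column(find1("genes.tsv"))
    cells <- .read_id_column(find1("barcodes.tsv"))
    if (length(genes) != nrow(m))
      stop("dimension mismatch: matrix has ", nrow(m), " rows but genes.tsv has ",
           length(genes), " entries")
    if (length(cells) != ncol(m))
      stop("dimension mismatch: matrix has ", ncol(m),
           " columns but barcodes.tsv has ", length(cells), " entries")
    dimnames(m) <- list(genes, cells)
    meta_path <- cell_meta %||% {
      cm <- file.path(path, "cell_meta.tsv")
      if (file.exists(cm)) cm else NULL
    }
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    if (grepl("\\.mtx(\\.gz)?$", path))
      stop("a bare .mtx needs companion genes.tsv/barcodes.tsv; ",
           "pass the directory containing them")
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                            comment.char = "#")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    meta_path <- cell_meta
  }
  cluster <- doublet <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, comment.char = "#")
    if (!"cell_id" %in% names(meta)) stop("cell metadata needs a cell_id column")
    idx <- match(colnames(m), meta$cell_id)
    if (anyNA(idx)) stop("cell metadata is missing ", sum(is.na(idx)), " cells")
    if ("cluster_label" %in% names(meta)) cluster <- meta$cluster_label[idx]
    if ("doublet_score" %in% names(meta)) doublet <- meta$doublet_score[idx]
  }
  expression_matrix(m, cluster = cluster, doublet_score = doublet)
}

.read_id_column <- function(path) {
  x <- utils::read.delim(path, header = FALSE)
  as.character(x[[1]])
}

#' Write a count matrix as a Matrix Market triplet directory
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `cell_meta.tsv`
#' (cluster labels and doublet scores, when present). The round trip
#' through [read_count_matrix()] restores the same sparse contents.
#'
#' @param x an `expression_matrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "expression_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read / write grayscale images
#'
#' PNG files are read with the png package (8-bit scale, values 0-255);
#' TIFF files with the tiff package at their native bit depth. Images with
#' more than one channel are rejected.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param gene,slice_id identifiers for the returned `ish_image`; default
#'   from the file name (`<gene>__<slice>.png`).
#' @return an `ish_image`.
#' @export
read_image <- function(path, gene = NULL, slice_id = NULL) {
  if (!file.exists(path)) stop("missing input: no such image file: ", path)
  base <- sub("\\.[^.]+$", "", basename(path))
  parts <- strsplit(base, "__", fixed = TRUE)[[1]]
  gene <- gene %||% parts[1]
  slice_id <- slice_id %||% (if (length(parts) > 1) parts[2] else "slice1")
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) stop("non-grayscale image: ", path)
    round(a * 255)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    a <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(a)) == 3) stop("non-grayscale image: ", path)
    a
  } else stop("unsupported image format: ", path)
  ish_image(px, gene = gene, slice_id = slice_id)
}

#' @rdname read_image
#' @param img an `ish_image` or matrix with values in \[0, 255\].
#' @export
write_image <- function(img, path) {
  px <- .pixels(img)
  stopifnot(min(px) >= 0, max(px) <= 255)
  if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(px / 255, path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  else stop("unsupported image format: ", path)
  invisible(path)
}

#' Read an ROI set from a label image or polygon JSON
#'
#' Label images code pixels 0 = outside, 1-4 = the four layers in the fixed
#' order SuG, Op, InG/InWh, DpG, 5 = background. Polygon files are JSON
#' objects mapping each of the five region names (`SuG`, `Op`, `InG/InWh`,
#' `DpG`, `background`) to a list of `[row, col]` vertices (0-based pixel
#' coordinates); polygons are rasterized with even-odd fill over pixel
#' centers, which requires the image size under key `image_size`.
#'
#' @param path `.png`/`.tif` label image or `.json` polygon file.
#' @return an `roi_set`.
#' @export
read_roi_set <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(spec$image_size))
      stop("polygon ROI file needs an image_size field")
    sz <- as.integer(spec$image_size)
    need <- c(SC_LAYERS, "background")
    masks <- lapply(need, function(nm) {
      poly <- spec$rois[[nm]]
      if (is.null(poly)) stop("polygon ROI file is missing region: ", nm)
      rasterize_polygon(as.matrix(poly), sz)
    })
    names(masks) <- need
    return(roi_set(masks[SC_LAYERS], masks$background))
  }
  lab <- .pixels(read_image(path))
  masks <- lapply(1:4, function(v) lab == v)
  names(masks) <- SC_LAYERS
  roi_set(masks, lab == 5)
}

#' @rdname read_roi_set
#' @param rois an `roi_set`.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  lab <- array(0, dim(rois$background))
  for (i in 1:4) lab[rois$layers[[i]]] <- i
  lab[rois$background] <- 5
  write_image(lab, path)
}

#' Rasterize a polygon with even-odd fill
#'
#' Marks every pixel whose center lies inside the polygon under the
#' even-odd rule (a ray from the pixel center crosses the polygon boundary
#' an odd number of times). Coordinates are 0-based `[row, col]` vertices.
#'
#' @param vertices n x 2 matrix of `[row, col]` polygon vertices.
#' @param size `c(rows, cols)` of the target grid.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(vertices, size) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 3)
  nr <- size[1]; nc <- size[2]
  py <- v[, 1]; px <- v[, 2]
  qy <- c(py[-1], py[1]); qx <- c(px[-1], px[1])
  rows <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  inside <- matrix(FALSE, nr, nc)
  for (e in seq_along(py)) {   # horizontal-ray crossing test per edge
    y1 <- py[e]; y2 <- qy[e]; x1 <- px[e]; x2 <- qx[e]
    if (y1 == y2) next
    crosses <- ((rows >= pmin(y1, y2)) & (rows < pmax(y1, y2))) &
      (cols < x1 + (rows - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses)
  }
  inside
}

#' Write a data frame as TSV with a provenance header
#'
#' Every output table starts with a `#` comment carrying the package
#' version and, when a config is given, a hash of the configuration.
#'
#' @param df data.frame.
#' @param path output path.
#' @param cfg optional `spaced_config` for the provenance hash.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}

#' Write a simulated study bundle to disk
#'
#' Lays out the study as plain files: the triplet count matrix (with cell
#' metadata), per-slice PNG images under `images/`, an ROI label image, a
#' manifest of the image files, and a ground-truth JSON.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(study, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(study$expr, file.path(dir, "counts"))
  write_roi_set(study$ish$rois, file.path(dir, "rois.png"))
  manifest <- do.call(rbind, lapply(names(study$ish$images), function(g) {
    slices <- study$ish$images[[g]]
    files <- vapply(slices, function(s)
      file.path("images", sprintf("%s__%s.png", g, s$slice_id)), character(1))
    for (j in seq_along(slices))
      write_image(slices[[j]], file.path(dir, files[j]))
    data.frame(gene = g,
               slice_id = vapply(slices, `[[`, character(1), "slice_id"),
               file = files)
  }))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study bundle from disk
#'
#' Loads what [write_bundle()] wrote. Every image listed in the manifest
#' must exist; a missing file raises a stage-labeled missing-input error.
#'
#' @param dir bundle directory.
#' @return list with `expr`, `ish` (`images`, `rois`) and `truth` (if
#'   present), mirroring [simulate_study()].
#' @export
read_bundle <- function(dir) {
  expr <- read_count_matrix(file.path(dir, "counts"))
  rois <- read_roi_set(file.path(dir, "rois.png"))
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("missing input: no manifest.tsv in ", dir)
  manifest <- utils::read.delim(man_path)
  images <- list()
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f))
      stop("missing input: image listed in manifest not found: ", f)
    img <- read_image(f, gene = manifest$gene[i],
                      slice_id = manifest$slice_id[i])
    images[[manifest$gene[i]]] <- c(images[[manifest$gene[i]]], list(img))
  }
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  list(expr = expr, ish = list(images = images, rois = rois), truth = truth)
}
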