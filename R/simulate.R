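#' Configuration of the synthetic study generator
#'
#' Defines a synthetic study: a gene x cell UMI count matrix with
#' subtype-restricted marker genes planted on a negative-binomial
#' background, and layered ISH-like images with layer-specific signal-pixel
#' densities. Defaults describe a small but realistic droplet-style
#' experiment — 4 neuron subtypes of 100 cells each, 2000 genes of which 10
#' per subtype are markers enriched `marker_fold`-fold, overdispersed NB
#' counts (mean 2, dispersion 0.5), 2% mitochondrial and 2% spike-in
#' genes — and ISH slices of 100 x 100 pixels with four horizontal layer
#' bands of 20% of the rows each (the rest is the background strip),
#' signal-pixel density 0.4 inside a gene's true layer and 0.02 elsewhere,
#' and Gaussian pixel noise of sd 10 on the 8-bit scale.
#'
#' @param n_subtypes,cells_per_subtype,n_genes,n_markers_per_subtype counts.
#' @param marker_fold mean fold enrichment of a marker in its own subtype
#'   (> 1; `1` simulates the null of no markers).
#' @param nb_mean,nb_dispersion negative-binomial background mean and
#'   dispersion (variance = mean + dispersion * mean^2).
#' @param mito_gene_fraction,ercc_gene_fraction fraction of genes labeled
#'   as mitochondrial / ERCC spike-ins.
#' @param image_size `c(rows, cols)` of simulated slices.
#' @param layer_band_fractions 4 row fractions of the layer bands
#'   (sum < 1; the remaining rows form the background strip).
#' @param signal_density_in,signal_density_out Bernoulli signal-pixel
#'   densities inside / outside a gene's true layer.
#' @param noise_sd Gaussian pixel noise sd (8-bit scale).
#' @param slices_per_gene ISH slices simulated per gene.
#' @param seed RNG seed; identical seed + config give identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subtypes = 4, cells_per_subtype = 100,
                       n_genes = 2000, n_markers_per_subtype = 10,
                       marker_fold = 8, nb_mean = 2, nb_dispersion = 0.5,
                       mito_gene_fraction = 0.02, ercc_gene_fraction = 0.02,
                       image_size = c(100, 100),
                       layer_band_fractions = rep(0.2, 4),
                       signal_density_in = 0.4, signal_density_out = 0.02,
                       noise_sd = 10, slices_per_gene = 2, seed = 1) {
  stopifnot(n_subtypes >= 1, cells_per_subtype >= 1, n_genes >= 1,
            n_markers_per_subtype >= 1, marker_fold >= 1,
            nb_mean > 0, nb_dispersion > 0,
            length(image_size) == 2, all(image_size >= 2),
            length(layer_band_fractions) == 4,
            all(layer_band_fractions > 0),
            signal_density_in >= 0, signal_density_in <= 1,
            signal_density_out >= 0, signal_density_out <= 1,
            noise_sd >= 0, slices_per_gene >= 1)
  if (sum(layer_band_fractions) > 1)
    stop("layer_band_fractions must sum to at most 1")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an expression matrix with planted markers
#'
#' Counts are drawn from a negative binomial with gene-specific baseline
#' means (log-normal around `nb_mean`) and dispersion `nb_dispersion`; a
#' marker gene's mean is multiplied by `marker_fold` in the cells of its
#' own subtype. A fraction of genes is renamed with a mitochondrial
#' (`mt-`) or spike-in (`ERCC-`) prefix so QC fields are exercised, and
#' each cell gets a doublet score drawn from a Beta(1, 30) (almost all
#' below the usual 0.16 cutoff).
#'
#' @param config a `sim_config`.
#' @return list with `matrix` (an `expression_matrix` with cluster labels
#'   and doublet scores) and `truth` (list: `labels`, `markers` — named
#'   list subtype -> marker gene ids).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .sim_expression(config)
}

.sim_expression <- function(cf) {
  n_cells <- cf$n_subtypes * cf$cells_per_subtype
  subtypes <- sprintf("Ex-%d", seq_len(cf$n_subtypes))
  labels <- rep(subtypes, each = cf$cells_per_subtype)

  gene_ids <- sprintf("Gene%04d", seq_len(cf$n_genes))
  n_mito <- round(cf$mito_gene_fraction * cf$n_genes)
  n_ercc <- round(cf$ercc_gene_fraction * cf$n_genes)
  special <- sample(cf$n_genes, n_mito + n_ercc)
  if (n_mito) gene_ids[special[seq_len(n_mito)]] <-
    sprintf("mt-Gene%03d", seq_len(n_mito))
  if (n_ercc) gene_ids[special[n_mito + seq_len(n_ercc)]] <-
    sprintf("ERCC-%05d", seq_len(n_ercc))

  plain <- setdiff(seq_len(cf$n_genes), special)
  marker_idx <- sample(plain, cf$n_subtypes * cf$n_markers_per_subtype)
  markers <- split(marker_idx,
                   rep(subtypes, each = cf$n_markers_per_subtype))

  base_mean <- cf$nb_mean * stats::rlnorm(cf$n_genes, -0.125, 0.5)
  size <- 1 / cf$nb_dispersion
  mu <- matrix(base_mean, cf$n_genes, n_cells)
  for (k in subtypes)
    mu[markers[[k]], labels == k] <- mu[markers[[k]], labels == k] * cf$marker_fold
  counts <- matrix(stats::rnbinom(length(mu), size = size, mu = mu),
                   cf$n_genes, n_cells,
                   dimnames = list(gene_ids,
                                   sprintf("cell%04d", seq_len(n_cells))))
  doublet <- stats::rbeta(n_cells, 1, 30)
  em <- expression_matrix(counts, cluster = labels, doublet_score = doublet)
  list(matrix = em,
       truth = list(labels = labels,
                    markers = lapply(markers, function(i) sort(gene_ids[i]))))
}

# horizontal-band ROI geometry shared by all slices of a study
.band_rois <- function(cf) {
  nr <- cf$image_size[1]; nc <- cf$image_size[2]
  band_rows <- floor(cf$layer_band_fractions * nr)
  if (any(band_rows < 1)) stop("image too small for the layer bands")
  if (sum(band_rows) >= nr)
    stop("layer bands leave no rows for the background strip")
  starts <- cumsum(c(1, band_rows))
  masks <- lapply(seq_len(4), function(i) {
    m <- matrix(FALSE, nr, nc)
    m[starts[i]:(starts[i + 1] - 1), ] <- TRUE
    m
  })
  names(masks) <- SC_LAYERS
  bg <- matrix(FALSE, nr, nc)
  bg[starts[5]:nr, ] <- TRUE
  roi_set(masks, bg)
}

#' Simulate one layered ISH-like slice
#'
#' The image is divided into four horizontal layer bands plus a background
#' strip. Signal pixels are drawn Bernoulli(`signal_density_in`) inside the
#' gene's true layer and Bernoulli(`signal_density_out`) everywhere else;
#' signal pixels get a high intensity (200), non-signal a low one (30),
#' Gaussian noise of sd `noise_sd` is added, and values are clipped to
#' \[0, 255\].
#'
#' @param config a `sim_config`.
#' @param true_layer the gene's true layer (one of `"SuG"`, `"Op"`,
#'   `"InG/InWh"`, `"DpG"`), or `NA` for a gene with no layer preference.
#' @param gene,slice_id identifiers stamped on the image.
#' @return list with `image` (`ish_image`), `rois` (`roi_set`) and
#'   `truth_mask` (the planted logical signal mask).
#' @export
simulate_ish_image <- function(config = sim_config(), true_layer = "SuG",
                               gene = "GeneSim", slice_id = "slice1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .sim_ish_image(config, true_layer, gene, slice_id)
}

.sim_ish_image <- function(cf, true_layer, gene, slice_id,
                           rois = .band_rois(cf)) {
  if (!is.na(true_layer) && !true_layer %in% SC_LAYERS)
    stop("unknown layer: ", true_layer)
  nr <- cf$image_size[1]; nc <- cf$image_size[2]
  dens <- matrix(cf$signal_density_out, nr, nc)
  if (!is.na(true_layer)) dens[rois$layers[[true_layer]]] <- cf$signal_density_in
  sig <- matrix(stats::runif(nr * nc) < dens, nr, nc)
  px <- ifelse(sig, 200, 30) + stats::rnorm(nr * nc, 0, cf$noise_sd)
  px <- pmin(pmax(px, 0), 255)
  list(image = ish_image(px, gene = gene, slice_id = slice_id),
       rois = rois, truth_mask = sig)
}

#' Simulate a complete study with known ground truth
#'
#' Composes the expression and image generators: an expression matrix with
#' planted markers, plus `slices_per_gene` ISH slices for every planted
#' marker gene, where subtype `i`'s markers are truly expressed in layer
#' `i` (SuG, Op, InG/InWh, DpG in order, recycled if more than 4 subtypes).
#' Everything is reproducible from `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list with `expr` (`expression_matrix`), `ish` (list: `images` —
#'   gene -> list of `ish_image`; `rois` — shared `roi_set`), and `truth`
#'   (list: `labels`, `markers`, `subtype_layer` — named vector subtype ->
#'   true layer, `gene_layer` — named vector marker gene -> true layer).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ex <- .sim_expression(config)
  subtypes <- names(ex$truth$markers)
  subtype_layer <- setNames(
    SC_LAYERS[(seq_along(subtypes) - 1) %% 4 + 1], subtypes)
  rois <- .band_rois(config)
  images <- list()
  gene_layer <- character(0)
  for (k in subtypes) {
    for (g in ex$truth$markers[[k]]) {
      gene_layer[[g]] <- subtype_layer[[k]]
      images[[g]] <- lapply(seq_len(config$slices_per_gene), function(s)
        .sim_ish_image(config, subtype_layer[[k]], g,
                       sprintf("slice%d", s), rois = rois)$image)
    }
  }
  list(expr = ex$matrix,
       ish = list(images = images, rois = rois),
       truth = list(labels = ex$truth$labels, markers = ex$truth$markers,
                    subtype_layer = subtype_layer, gene_layer = gene_layer))
}
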