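---
title: "Mapping transcriptomic subtypes onto tissue layers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcriptomic subtypes onto tissue layers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`spaced` answers one question: given transcriptomic neuron subtypes from a
dissociated single-nucleus RNA-seq experiment, in which lamina of a layered
structure does each subtype live? It does so indirectly, through marker
genes: if a subtype's most specific markers all stain one layer in ISH
images, the subtype is placed there. The chain of inference therefore rests
on two assumptions worth making explicit:

* **Markers carry the location.** The subtype's spatial distribution is
  read off the ISH pattern of its top marker genes. Markers expressed by
  several cell types, or subtypes without strongly restricted markers,
  weaken the inference — which is why marker selection ranks by a
  specificity score rather than by significance alone.
* **ISH area fraction is a usable proxy for expression.** The fraction of
  above-threshold pixels in a layer ROI approximates how broadly the gene
  is expressed there. It saturates for very strong staining and is blind to
  per-cell intensity differences below/above threshold.

```{r, eval = FALSE}
library(spaced)
study <- simulate_study(sim_config(seed = 7))
res <- run_spaced(study$expr, study$ish)
res$summary
```

## The pipeline, stage by stage

### Quality control

Cells are retained when all bounds hold, inclusively on the keep side:
`n_gene_min <= nGene <= n_gene_max` (defaults 800 and 6000),
`nUMI <= 20000`, mitochondrial UMI fraction `<= 3%`, and, when a doublet
score table is supplied, score `<= 0.16`. Genes must be detected (count
> 0) in at least 3 cells. The droplet-data defaults live in
`qc_presets("snrna")`; `qc_presets("patchseq")` carries the analogous
bounds for full-length patch-seq data (nGene 200–10000, mito <= 10%,
ERCC spike-in fraction <= 5%, genes in >= 2 cells). All bounds use the
same inclusive-keep semantics; for data exactly on a boundary this is the
generous reading. Doublet scores are consumed, never computed — the
package takes a `(cell_id, doublet_score)` TSV from whatever doublet
caller was used upstream.

The QC report records, for every dropped cell, the *first* rule it failed,
in the fixed order nGene-min, nGene-max, nUMI, mito, ERCC, doublet; a cell
failing several rules is counted once.

### Normalization and differential expression

Counts are log-normalized per cell, `x = ln(1 + s * c / nUMI)` with
`s = 10^4`. The one-vs-rest Wilcoxon rank-sum test is implemented
in-package because the standard implementation cannot compute exact
p-values in the presence of ties: for total group size `n <= 10` the
p-value is obtained by enumerating all `C(n, n1)` assignments of the
midranked observations to the two groups and counting assignments whose
rank-sum deviates from its expectation at least as much as observed; above
that, the normal approximation with tie and continuity correction is used.
The switch point is a compromise between exactness and the `C(n, n1)`
enumeration cost; at `n = 10` the two routes already agree closely.
Benjamini–Hochberg adjustment (via `stats::p.adjust`) is applied per
subtype across all genes tested.

A gene is flagged as a DEG only when it is *enriched*: `p_adj < 0.05` and
`log_fc >= 0.25` (difference of mean log-normalized expression, natural
log). The positive-direction requirement is a design choice — layer markers
are by construction genes the subtype expresses more than the rest, and
without it strongly depleted genes would enter the reference lists. The ROC
route flags on classification power `|2*AUC - 1| > 0.4` with the same
direction requirement (default margin 0); the raw AUC is also reported for
users who want the one-sided quantity.

### Specificity score and marker selection

For gene `g`, the mean log-normalized expression across the `K` subtypes is
normalized to a probability vector `p_g`, and for each subtype `k`

\[ S_{gk} = 1 - \sqrt{\mathrm{JSD}(p_g, e_k)} \]

with `e_k` the one-hot distribution on subtype `k` and JSD computed with
base-2 entropies (`0 log 0 = 0`), so `JSD` and `S` both live in `[0, 1]`.
This is the standard Jensen–Shannon specificity construction used for
tissue- and cell-type-specificity scoring; it equals 1 exactly when the
gene is expressed nowhere else, and spreading a fixed expression mass over
more subtypes strictly lowers it. The score used for ranking a subtype's
DEGs is `S_gk` for that same subtype (not the maximum over subtypes):
ranking is a within-subtype operation and the one-hot target makes the
own-subtype column the natural choice. Ties are broken by smaller adjusted
p-value, then lexicographic gene id, making the selection fully
deterministic. The top `n = 10` genes form the reference list; the scoring
stage was designed around panels of about that size, and fewer genes make
the layer ANOVA (genes are its replicates) increasingly underpowered.

### ISH quantification

Each slice is min–max rescaled to 8-bit (`[0, 255]`, round half up; a
constant slice maps to zeros), which also makes the whole quantification
invariant to constant intensity offsets. Thresholding uses the IsoData
intermeans rule on the 256-bin histogram — the default automatic method of
the common image-analysis tools — iterating
`t <- floor((mean_below(t) + mean_above(t)) / 2)` from the image mean to a
fixed point; signal pixels are those `>= t + 1`. A `--manual-threshold`
override exists for slices where the automatic level is unsatisfactory.
Each slice is thresholded independently (levels are per-slice, not per
gene): staining intensity varies between slices, and a per-gene level
would let one dark slice silence the others.

The area fraction of a layer ROI is the percentage of its pixels marked as
signal. From each layer's area fraction the background ROI's area fraction
is subtracted; negative differences are clipped to 0, since a layer dimmer
than the weakest-signal region carries noise, not signal. Slices of a gene
are combined by the arithmetic mean of their per-layer intensities —
slices are treated as replicates of equal standing. ROIs (including the
background region) are *inputs*, as in the published manual workflow:
masks come from a label image (0 outside, 1–4 the layers, 5 background) or
a JSON polygon file rasterized with an even-odd fill over pixel centers.
`propose_background()` offers a sliding-window minimal-mean suggestion and
is explicitly labeled an extension.

### Layer scores, ANOVA, assignment

Per gene the four intensities are min–max normalized to `[0, 1]` (a gene
with equal intensity everywhere becomes all zeros and contributes no
preference). The layer specificity score is
`ln(mean over genes + epsilon)` with `epsilon = 1e-3`; the offset keeps
zero-mean layers finite, and since `ln` is monotone the score *ordering*
is epsilon-free. Inference never runs on the scores: the one-way ANOVA
(layers as groups, genes as replicates) and the Tukey HSD post hoc run on
the normalized intensities themselves — the last processing step before
the test — so the log transform is purely a display scale. Tukey HSD was
chosen as the post hoc because the comparison is all six layer pairs at a
controlled family-wise level. If the normalized intensities carry no
variation at all the ANOVA is reported as `F = 0, p = 1` rather than
undefined.

A subtype is assigned its top-scoring layer only when the ANOVA `p <
alpha` *and* the winner's Tukey p against every other layer is `< alpha`
(default 0.05). Requiring the pairwise sweep is stricter than the ANOVA
alone; it encodes the conservative reading that a subtype whose best layer
is not separated from the runner-up may genuinely span multiple laminae
and should stay `unassigned`. Both the ANOVA and the post hoc p-values are
returned, so users who prefer the ANOVA-only rule can apply it themselves.
Subtypes with fewer than two quantifiable reference genes cannot be tested
and are returned unassigned. An assigned layer is by construction always
the score argmax.

### Missing images

`run_spaced` distinguishes two situations. A reference gene that simply has
no images in the supplied set is dropped with a warning — with stochastic
marker selection the chosen list can occasionally include a gene outside
the prepared panel, and degrading to fewer genes (ultimately to
`unassigned`) is the honest outcome. A gene whose images are *declared*
(listed in a bundle manifest) but missing on disk is a hard, stage-labeled
error: that is a broken input, not a smaller one.

## The synthetic-data generator

`simulate_study()` produces a complete study with known truth. Expression:
negative-binomial counts (the standard overdispersed model for UMI data)
with log-normal gene-level baseline means around `nb_mean = 2` and
dispersion 0.5, 2000 genes × 4 subtypes × 100 cells; 10 planted markers
per subtype whose mean is multiplied by `marker_fold = 8` in their own
subtype; 2% of genes renamed as mitochondrial and 2% as ERCC spike-ins so
the QC fields are exercised; per-cell doublet scores from a Beta(1, 30).
With these sizes a simulated cell detects roughly 1500 genes, which places
the synthetic data inside the same QC window used for real droplet data —
the pipeline runs on it unmodified. Images: four horizontal layer bands of
20% of the rows each plus a 20% background strip; signal pixels are
Bernoulli with density 0.4 inside a marker's true layer and 0.02
elsewhere; signal/non-signal pixels take intensities 200/30 with Gaussian
noise (sd 10) and clipping to `[0, 255]`. Band geometry stands in for
curved laminae deliberately: quantification is mask-driven, so ROI shape
is irrelevant to correctness. Everything derives from a single integer
seed through R's default RNG stream, so a seed plus a config reproduces a
study byte for byte.

What the generator does *not* emulate: ambient RNA and batch effects,
marker genes shared between subtypes, cross-slice registration error,
staining gradients and section artifacts, and ISH backgrounds that vary
within a slice. Passing the recovery experiments therefore demonstrates
that the machinery is correct and well-calibrated under its stated model,
not that real atlas images are this clean.

## Validation setup

The test suite validates every statistic against an independent oracle
(exact enumeration for the rank-sum test, the step-up formula for BH,
closed-form mean squares plus the F and studentized-range distribution
functions for ANOVA/Tukey, a brute-force entropy implementation for the
specificity score) and runs two recovery experiments: 50 seeded studies at
the default effect sizes, requiring at least 95% correct subtype–layer
assignments, zero wrong-layer assignments and at least 95% marker
recovery in the top-10 lists; and 20 null studies with equal in/out signal
densities, requiring at least 95% of runs to return every subtype
unassigned. These problem sizes keep the full suite within a few minutes
while leaving the binomial error of the measured rates well below the
margins being asserted.

## Limitations

* Layer count and names are fixed at the four SC laminae; generalizing to
  other layered structures needs only the ROI conventions relaxed, but is
  not exposed today.
* The correlation mapper (`map_clusters_by_correlation`) operates on mean
  profiles (optionally externally batch-integrated); it does not perform
  CCA-style integration itself, so cross-platform mappings inherit
  whatever batch structure the inputs carry.
* PNG images are read at 8-bit scale; 16-bit sources should come as TIFF.
* Area-fraction quantification ignores staining intensity above threshold;
  genes whose layers differ in intensity but not extent of staining are
  invisible to it.
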