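---
title: "SOM portrayal of spatial transcriptomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SOM portrayal of spatial transcriptomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical procedure implemented by
`spotsom`, the choices behind its defaults, and what its synthetic
benchmark does and does not demonstrate.

## The portrayal model

Spot-level spatial transcriptomics yields a genes × spots count matrix
$C_{gj}$ and hexagonal array coordinates per spot. Each spot is treated as
a micro-bulk sample. The analysis chain is:

1. **Gene filtering.** Genes detected ($C_{gj} > 0$) in fewer than
   `min_spots_expressed` spots (default 3) or with zero variance are
   dropped. Constant and all-zero profiles carry no information for the
   map and act as degenerate training samples.
2. **Library-size normalization.** Each spot column is scaled to a common
   total: the median library size by default (keeps values on a count-like
   scale), or 10,000 (`counts_per_10k`).
3. **Log transform.** $e_{gj} = \log_2(\text{norm}_{gj} + 1)$. The
   pseudocount (default 1) keeps zeros at zero; base 2 makes differences
   read as fold changes.
4. **Centralization.** $x_{gj} = e_{gj} - \bar e_{g\cdot}$, per gene across
   spots. This is what makes portraits *signed*: positive metagene values
   mean overexpression relative to that gene's section-wide average. The
   receptor–ligand module deliberately works on the pre-centralization
   log scale, because "expressed vs not expressed" is a detection
   question, whereas centralized values are relative levels.
5. **SOM training.** Gene profiles $x_g \in \mathbb{R}^{n_\text{spots}}$
   are the training samples; the map is a `grid_rows` × `grid_cols`
   rectangular grid (default 50 × 50 = 2,500 units) of prototype profiles
   ("metagenes"). Online Kohonen updates: at step $t$ with sample $x$,
   the best-matching unit $b = \arg\min_u \lVert x - w_u \rVert$ is found
   and every unit is moved by
   $\Delta w_u = \alpha(t)\, h_{ub}(t) (x - w_u)$ with Gaussian
   neighbourhood $h_{ub} = \exp(-d_{ub}^2 / 2\sigma(t)^2)$ on grid
   distance $d_{ub}$.
6. **Portraits.** Spot $j$'s portrait is the matrix of the $j$-th
   components of all $w_u$; group portraits average portraits over a spot
   group (typically user-supplied clusters — the package never computes
   spot clusters itself).

The key assumption is that co-expressed genes — genes with correlated
spatial profiles — are attracted to the same map region, so the portrait
of a spot decomposes its transcriptional state into a small number of
contiguous "module" blobs that are positionally comparable across spots.

## Training schedule

The schedule follows Kohonen's classic two-phase recipe:

* **Ordering phase** (first 35% of steps): the neighbourhood radius decays
  exponentially from `initial_radius` (default `max(grid)/2`) to
  `final_radius` (default 1). This is where the global topology forms.
* **Convergence phase** (remaining 65%): the radius stays at its final
  value while the learning rate keeps decaying; prototypes specialize
  locally. A long convergence phase sharpens the boundary between module
  regions and the flat background of the map, which matters for module
  extraction: with a schedule that only reaches the final radius at the
  very last step, module regions remain blurred into their surroundings
  and module gene lists pick up unrelated genes.

The learning rate decays exponentially from 0.5 to 0.01 over all steps.
The Gaussian $\sigma$ is `radius/2`, so the nominal radius bounds the
effectively updated neighbourhood (at distance $r$, $h = e^{-2} \approx
0.14$). Default 20 epochs (passes over the genes). All of these are
exposed in `som_config()`.

**Determinism.** The per-epoch sample orders (and random initialization,
if selected) are drawn in R under `set.seed(config$seed)`; the C++ core is
purely arithmetic. Two runs with one seed are bit-identical. The
neighbourhood update skips units with $h < 10^{-8}$ — a fixed cutoff, so
it cannot introduce run-to-run variation.

**Initialization.** Default `pca_plane`: units are laid out on the plane
of the first two principal axes of the gene profiles, spanning ±2
standard deviations; this is reproducible without randomness and starts
the map already "unfolded". `random` initialization (Gaussian with the
data's moments) is available; the quantization-error contract (final ≤
initial) is asserted for both in the test suite.

**Ties.** Best-matching-unit ties are resolved to the lowest row, then
lowest column (row-major first minimum). Exact ties occur with
constructed data and must not depend on memory layout.

## Module extraction

`overexpression_modules()` marks, in each supplied portrait, the units
above that portrait's `threshold_quantile` quantile (default 0.9), unions
the marks across portraits, and keeps 8-connected components with at
least `min_units` units (default 4, suppressing speckle components).
Labels A, B, … are assigned by decreasing unit count, then by top-left
position, so labelling is deterministic; labels are dataset-specific and
carry no meaning across datasets. Underexpression uses the same machinery
with the sign flipped; single-spot mode feeds every spot's own portrait.
K-means (`stats::kmeans` on the codebook), correlation clustering
(grid-adjacent units linked at Pearson correlation ≥ threshold) and
distance-map segmentation (units above a U-matrix quantile become
boundaries) are alternative views; the first two partition the grid.

The per-spot activity of a module is the mean of its metagenes'
components at that spot (`module_spatial_score`), the quantity used to
colour the tissue image.

## Enrichment

Module × gene-set overrepresentation uses the one-sided hypergeometric
test with Benjamini–Hochberg FDR across all pairs. The universe defaults
to the genes retained after filtering — using the whole annotation would
inflate significance for every detected-gene set. The test suite checks
the p-value against an explicit binomial-coefficient tail sum and checks
null calibration by Kolmogorov–Smirnov on 2,000 random modules; for that
check the module/set/universe sizes (8,000 / 12,000 / 25,000) are chosen
large so the discrete null support is much finer than the KS critical
distance — with desk-scale sizes the p-value lattice itself, not
miscalibration, would fail the comparison.

## Receptor–ligand calls and pathway signal flow

Per spot and pair, the state is `coexpressed` / `receptor_only` /
`ligand_only` / `none` by strict comparison of the two log-scale values
against `expr_threshold` (default 0; a value exactly at the threshold
counts as not expressed — a deterministic edge rule). The joint score of a
coexpressed pair is the mean of the two values; colour saturation is the
relevant value over the pooled 95th percentile of the two genes, clipped
to [0, 1]. Pathway-wide maps fold per-pair calls with the precedence
coexpressed > receptor_only > ligand_only > none, keeping the
best-scoring pair in the winning state. Only same-spot co-expression is
called: a spot is a micro-bulk of several cells, so co-detection within
one spot is the natural unit of evidence; cross-spot signalling is out of
scope. Neighbourhood queries use the hex-lattice distance on Visium
"doubled-width" array coordinates ($d = \Delta r + \max(0, (\Delta c -
\Delta r)/2)$).

Pathway signal flow propagates positive node values (the log base raised
to the node genes' mean centralized expression in a cluster, so 1 is
neutral) through a signed directed graph in topological order: a node's
signal is its own value times the geometric mean of its parents'
contributions, where activation contributes the parent's signal and
inhibition its reciprocal. Cycles are collapsed to single nodes valued at
the geometric mean of their members — an explicit approximation, reported
as such. This propagation rule is this package's declared design (the
qualitative contract is source-to-sink flow through the topology); it is
multiplicative so that chains compose as products and neutral inputs stay
neutral, and it is isolated behind `propagate_psf()` so an alternative
rule can be swapped in.

## The synthetic benchmark

`generate_synthetic()` emulates the structure the method is meant to
detect: a hex lattice (default 20 × 20 spots) partitioned into
`n_domains` (4) contiguous domains via hex-distance Voronoi cells of
random centres; one planted module of `genes_per_module` (50) genes per
domain with negative-binomial mean `base_mean × fold_change` (5 × 4)
inside the domain and `base_mean` outside; `n_background_genes` (500)
unstructured genes; per-spot library sizes log-normal around 5,000
(CV ≈ 0.25); dispersion 0.5 (variance $\mu + 0.5\mu^2$). Defaults were
chosen once as a realistic desk-scale regime: a four-fold expression
change is a strong but common magnitude for regional programs, and NB
dispersion 0.5 is within the range typical for spot-level counts.

What it does **not** emulate: cell-type mixtures within spots, smooth
spatial gradients, spot-to-spot bleed-over, batch effects, or the
gene–gene correlation structure of real transcriptomes. Passing the
recovery benchmark therefore shows that the implementation finds planted
co-expression structure under overdispersed counts — not that it resolves
arbitrary real tissue. Occasional seeds place two Voronoi centres so
close that a domain is tiny; recovery is asserted across seeds (≥ 90%),
not per seed.

Problem sizes throughout the tests (700 × 400 matrices, 20 × 20 maps, 10
seeds) are the package's chosen desk-scale study conditions; the 50 × 50
default map is exercised directly where geometry, not recovery, is under
test.

## Degenerate inputs and numerical notes

* Spots with zero total counts abort normalization (they cannot be
  scaled); the error lists the barcodes.
* Non-finite values anywhere in the chain are fatal, not propagated.
* Centralized rows are zero-mean to floating tolerance (~1e-12 asserted).
* Constant codebook vectors have undefined Pearson correlation; the
  correlation segmentation treats them as unlinked rather than NA.
* Model archives store doubles as `%.17g` text, which round-trips IEEE
  doubles exactly; loading verifies the archive's format version and all
  members before constructing anything (no partial loads).
* The quantile threshold uses R's default (type 7) sample quantile.

## Known limitations

* The online trainer is single-threaded; a 50 × 50 map over ~18,000 genes
  and ~3,500 spots (a full Visium section) is hours of compute, consistent
  with heavy-duty offline portrayal workflows.
* Module labels are unstable across configurations by construction
  (relabelling follows component sizes).
* Enrichment is overlap-based (hypergeometric); no ranked or
  permutation-based gene-set statistic is provided.
* The pathway propagation rule is a declared, swappable choice; no claim
  of numerical equivalence to any published pathway-flow tool is made.
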