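---
title: "Methods: quantifying mammary morphogenesis with mammoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mammary morphogenesis with mammoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoquant)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter, what the synthetic generators do and
do not emulate, the numerical choices, and the known limitations. Everything
quantitative stated here is computed by the test suite or the acceptance
script; nothing is quoted from elsewhere.

## Whole-mount segmentation

A carmine-stained whole mount is a dark epithelial tree on a lighter, noisy
stromal background, digitized at a known dpi (`pixel_size_from_dpi()`
converts via 25,400 µm per inch; 2400 dpi gives ≈ 10.6 µm pixels, usually
reported as 10.5). `segment_tree()` runs a fixed chain:

1. **PCA grayscale.** RGB pixels are mean-centred and projected onto the
   first principal component of their 3×3 covariance — the maximum-variance
   grey axis of the stain. The sign is oriented so the projection correlates
   positively with Rec.709 luminance (dark epithelium stays dark), and the
   result is min–max rescaled to [0, 1]. Because centring, projection and
   rescaling commute with positive affine maps of the channels, the whole
   downstream mask is invariant to such transforms; this is why gamma
   adjustment (default 0.45, a contrast aid for carmine material) is applied
   to the *rescaled grayscale* rather than the raw channels — applied before
   the projection it would destroy that invariance while changing nothing
   else of substance.
2. **CLAHE** (tile 64 px, clip 2.0). Defaults were chosen for the
   ~10.5 µm/px whole-mount scale: a 64 px tile is ~0.7 mm of tissue, large
   enough to contain both duct and stroma.
3. **Background subtraction.** A Gaussian blur with σ = 20 px (~200 µm,
   much wider than a duct) estimates the smooth background, which is
   subtracted (reflective boundary handling). The operation is deliberately
   not idempotent — it is a high-pass filter, not a projection.
4. **Otsu binarization.** `otsu_threshold()` maximizes the between-class
   variance on a 256-bin histogram, ties broken toward the lowest cut; a
   property test checks it against exhaustive search on random histograms.
   The darker class is the epithelium (guaranteed by the PCA orientation).
5. **Cleanup.** Closing (disk radius 2 px), removal of components below
   `min_object_px`, and selection of the connected component nearest the
   user-supplied nipple. The nipple is a required input: the tree origin is
   determined visually on the scan, and no auto-detection is attempted.

The lymph node — typically the darkest feature — is found by looping over
multilevel Otsu partitions (k = 2…6, computed exactly by dynamic
programming), taking connected components of the darkest class outside the
tree, and scoring each by solidity × a Gaussian weight on its area around an
expected size (default π·28² px with SD half of that). The first score above
0.5 wins; otherwise the best candidate; otherwise the node is reported
absent, which is a legitimate outcome. The score rule is an explicit,
reproducible stand-in for a visual "the boundary looks right" judgement;
`expected_area_px` and `area_tol_px` are configuration, not magic.

## Morphometry

**Boundary and area.** Contours are traced on the pixel-corner lattice (the
crack boundary between foreground and background), so the traced polygon of
an untouched mask encloses exactly the mask's pixel squares: its shoelace
area equals the pixel count, every mask pixel centre lies strictly inside,
and clipped Voronoi cell areas sum to the polygon area at machine precision.
The concave hull's tightness is set by a shrink factor `s`: `s = 1` traces
the exact contour, `s = 0` returns the convex hull, and intermediate values
close the mask with a disk of radius `r = ((1 − s)/s)·a` before tracing,
where `a` is the median interior distance-transform value (the duct
half-caliber). At the default `s = 0.5` the hull therefore smooths
concavities narrower than the duct's own thickness while tracking the mask
area within ~2% on generator trees; mapping `s` to a fraction of the tree's
*diameter* instead was rejected because it makes the default hull nearly
convex and inflates area by far more than the measurement error of interest.
At saddle points (diagonally touching pixels) the tracer turns toward the
current pixel, which keeps every loop simple at the cost of splitting
pinched regions; the largest loop is kept.

**Extension and lymph-node distance.** Ductal extension is the exhaustive
maximum of the nipple-to-vertex distance; the arg-max vertex is the leading
edge. The signed lymph-node distance projects both the leading edge and the
node centroid onto the outgrowth axis (nipple → leading edge) and takes the
difference — positive once the front has passed the node. Being a
difference of projections it is exactly rotation invariant, which the tests
verify to 1e-6 relative.

**Branch points.** The mask is thinned by Zhang–Suen iterations. Two
artefact classes of thinning on thick ducts must be handled before counting
forks: staircase patterns along diagonals (pixels with 3 *contiguous*
neighbours that are not forks — handled by requiring a Rutovitz crossing
number ≥ 3, i.e. three separate emanating branches, rather than a raw
neighbour count) and short terminal spurs (pruned up to the duct caliber).
Residual fork clusters are merged by single linkage within 5 px. Manual
curation of spurious forks (e.g. where independent ducts overlap in the 2-D
projection) is represented by an explicit, serializable `exclusions` list
rather than interactive edits, so every refinement is auditable. "Primary
branches" are all surviving merged branch points; no order-based hierarchy
is imposed, and the exclusion mechanism is the hook for stricter readings.

**Dirichlet territories.** Each branch point's territory is its Voronoi
cell clipped to the boundary polygon, computed exactly by intersecting the
polygon with perpendicular-bisector half-planes (Sutherland–Hodgman). No
unbounded cells are ever reported; areas come out in input-site order and
their coefficient of variation is the branching-consistency summary.

## Protrusion quantification

Masks (body, protrusions) are inputs, as in outline-on-the-image practice;
automatic segmentation of cysts is out of scope. The SUnSET-style localized
translation ratio divides the mean protrusion intensity by the mean over an
equal-area subregion of the peri-body band (non-body pixels within 10 µm of
the body, protrusions excluded), grown outward from the band pixels nearest
the protrusion root. If the band is smaller than the protrusion the whole
band is used, with a warning. Normalized region intensities divide by the
whole-cyst mean. Both are ratios of means of a single channel, hence
invariant to global rescaling — the tests assert this exactly. Background
correction (subtract a wide Gaussian, clip at 0) is available via
`bg_sigma` but off by default: subtraction changes ratios, and on unshaded
images the raw channel is the right denominator.

Tracking is greedy frame-to-frame IoU linking (threshold 0.3, best matches
first). Tracks are strictly contiguous — a one-frame disappearance closes
the track, matching the interpretation that a vanished protrusion has
retracted. Lifetime counts frames present times the frame interval,
inclusive of birth and death frames (time visible). Length is the maximal
geodesic distance from the body boundary within body ∪ protrusion
(8-neighbour chamfer with √2 diagonal steps), so curved protrusions are
measured along their extent; the chamfer metric overestimates oblique
straight-line paths by a few percent, which the tests budget for.

## Proteomic screen statistics

The preprocessing order is impute → filter → normalize
(`preprocess_abundance()`), configurable because the original ordering of
normalization versus imputation is ambiguous; the filter consults only the
`original_zero` provenance flags, never post-imputation values, so the
order cannot change which proteins are dropped. Imputation assigns zeros
half the global minimum positive intensity; the group-zero filter drops
proteins with more than two pre-imputation zeros in any single group; EIC
normalization divides by column totals.

`differential()` excludes proteins observed in fewer than 3 of the pooled
samples (read as 3-of-10 in the 5 + 5 design), runs two-tailed Welch tests,
attaches q-values (BH default; Storey's smoother-based π₀ as an option,
which only scales BH down), and computes log2 ratios of post-imputation
group means with ±10 sentinels for proteins uniquely observed in one group
("uniquely observed" is decided on the provenance flags). Significance is
the disjunction p < 0.05 or |log2| ≥ 2 (4-fold). Degenerate zero-variance
proteins get p = 1 when the means agree, p = 0 otherwise. A calibration
caveat the tests make explicit: the two-sided Welch test at n = 5 + 5 has a
true level slightly below nominal (~0.044 even on Gaussian data), so the
generator's replicate noise is kept at a modest log-SD of 0.15 (~15% CV) so
that null matrices stay inside the 0.05 ± 0.01 calibration band; measured
levels are pooled over several 2000-protein matrices to control Monte Carlo
noise.

Sample clustering uses distance 1 − Pearson correlation with average
linkage (UPGMA), after per-protein standardization (the heat-map
convention): without standardization the correlation is dominated by the
few most abundant proteins and group structure carried by hundreds of
mid-abundance proteins can be masked. `standardize = FALSE` restores the
plain correlation distance, and the linkage is verified against a
brute-force UPGMA enumeration. Random-forest stage classification trains
5000 trees on reference-stage profiles and scores samples by vote
fractions; determinism comes from a single integer seed, and out-of-bag
accuracy is the internal error estimate. Estimating an "optimal" number of
clusters is deliberately only a pluggable hook (`optimal_clusters()`,
average silhouette by default) — it is not part of the fitted pipeline.

`group_compare()` dispatches the study's three designs: ANOVA with
Tukey–Kramer post-hoc contrasts (studentized-range based, valid for unequal
n), exact two-sided Wilcoxon rank-sum for two groups, and Kruskal–Wallis
with tie correction followed by Dunn's z-tests (Holm-adjusted by default).

## Synthetic data: what it emulates, and what it does not

The generators provide exact ground truth so that every measurement above
can be validated without animal images or deposited MS data.

* `generate_wholemount()` grows a bifurcating tree by a random walk with
  jittered fork angles whose opening decays by 0.7 per generation — the
  decaying fan keeps subtrees from crossing, so the rendered mask has no
  enclosed holes and "truth area = pixel count" stays exact. Truth fields
  (area, extension, fork centres) are measured on the rendered mask, not on
  generative intent. Intensities are 8-bit with additive Gaussian noise
  clipped to [0, 255] (noise tests therefore use small SDs), and the RGB
  channels are a carmine-like weighting of one underlying field. Not
  emulated: stromal texture, stain gradients, fold artifacts, overlapping
  independent ducts (that artefact is represented downstream by the
  exclusions mechanism), and multi-gland scans.
* `generate_cyst_timelapse()` renders a disk-shaped body with radial
  finger protrusions at configurable compartment intensity ratios and
  presence windows. Body signal is painted 12 µm beyond the reported body
  mask, emulating conservative hand-drawn outlines, so the 10 µm
  quantification band lies on cell signal as it does in real images. Not
  emulated: protrusion curvature and branching, z-stack geometry, focal
  adhesion puncta, photobleaching.
* `generate_abundance_matrix()` draws per-protein baselines
  (log-normal across proteins, SD 1.5 on the natural-log scale around a
  mean of 18 ≈ 6.6 × 10⁷ ion counts), replicate noise of 15% CV, planted
  multiplicative fold-changes on the second group of a pair, and exact-zero
  dropout (default 5%) recorded in provenance flags. The default design is
  the study-style 3 groups × 5 samples. Not emulated: peptide-level
  effects, shared-peptide protein inference, intensity-dependent missingness
  (dropout is uniform, not abundance-dependent), batch effects.

Passing on these generators shows the measurement chain is correct and
calibrated under known conditions; it does not certify performance on real
scans with staining artifacts or real MS matrices with structured
missingness.

## Problem sizes and determinism

The test suite and acceptance script run at sizes chosen to make Monte
Carlo error small relative to the tolerances they check: 20 generator seeds
for whole-mount recovery (448² px canvases), 100 random histograms for the
Otsu oracle, a 2000² grid for the Voronoi oracle, 10–20 seeds for intensity
and classifier recoveries, and 10 × 2000 null proteins for the Welch
calibration. Every stochastic step takes an explicit integer seed, and
generators restore the caller's RNG state.

## Known limitations

* Zhang–Suen thinning is 8-connectivity topology-preserving but its
  junction positions sit up to (half duct width)/tan(half fork angle)
  beyond the geometric fork centre; branch *counts* are exact on the
  generator, branch *positions* are accurate to that offset.
* The crack-boundary tracer keeps the largest simple loop; masks pinched to
  single-pixel diagonal connections lose the pinched-off part from the
  boundary (not from the mask itself).
* The chamfer geodesic overestimates oblique distances by up to ~8%
  (√2-step metric); sub-pixel exact geodesics were not needed at the
  tolerances of interest.
* `segment_lymph_node()` assumes one node-like dark blob; multiple nodes
  return only the best-scoring one.
* All image operations are 2-D; z-projected inputs are the caller's
  responsibility.
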