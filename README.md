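# mammoquant

Quantitative tools for studies of pubertal mammary gland morphogenesis.

During puberty, terminal end buds at the tips of the rudimentary mammary
epithelium invade the fat pad and bifurcate repeatedly, building an arborized
ductal tree. Studies of this process quantify three very different kinds of
data, and `mammoquant` implements the complete analysis chain for each as
tested, reusable R code:

1. **Whole-mount morphometry.** Carmine-stained whole mounts scanned at
   known dpi (2400 dpi ⇒ 25,400/2400 ≈ 10.5 µm pixels) are segmented into a
   binary epithelial tree — PCA grayscale conversion, gamma/CLAHE contrast
   enhancement, wide-Gaussian (σ = 20 px) background subtraction, Otsu
   binarization, morphological cleanup — and then measured: tree area `A`
   from a concave boundary hull (shrink factor `s ∈ [0,1]`, default 0.5),
   ductal extension `E = max_v ‖v − nipple‖` over boundary vertices, primary
   branch count from skeleton branch points (Rutovitz crossing number ≥ 3,
   merged within 5 px), Dirichlet (Voronoi) tessellation of branch
   territories clipped to the boundary, and the signed distance from the
   lymph-node centroid to the epithelial leading edge along the outgrowth
   axis.
2. **Organoid protrusion quantification.** For 3D cyst/tubulogenesis assays:
   compartmentalized fluorescence readouts (mean intensity of a protrusion
   over a size-matched peri-body band — the SUnSET localized-translation
   ratio — and region means normalized to the whole-cyst mean), and
   protrusion dynamics from time-lapses by greedy IoU linking (lifetime =
   frames present × frame interval; length = maximal geodesic distance from
   the body boundary).
3. **Proteomic screen statistics.** Label-free MS downstream processing:
   half-global-minimum imputation of zeros, filtering of proteins with > 2
   pre-imputation zeros in any group, summed-EIC normalization, per-protein
   two-tailed Welch tests with Benjamini–Hochberg (or Storey) q-values,
   log2 mean ratios with ±10 sentinels for uniquely observed proteins and
   the `p < 0.05 and/or |log2| ≥ 2` significance rule, correlation/average-
   linkage sample clustering, 5000-tree random-forest stage classification,
   and the standard group tests (ANOVA + Tukey–Kramer, Wilcoxon rank-sum,
   Kruskal–Wallis + Dunn).

Every stage is exercised end-to-end on synthetic data with exact ground
truth: a bifurcating-tree renderer for whole mounts, a cyst/protrusion
time-lapse renderer, and a zero-inflated log-normal abundance generator with
planted fold-changes.

## Worked example

```r
library(mammoquant)

## whole mount: generate -> segment -> measure
wm  <- generate_wholemount(tree_gen_params(seed = 11, ln_center_px = c(120, 340)))
seg <- segment_tree(wm$image, nipple_px = wm$truth$nipple_px)
measure_gland(seg)
#> # A tibble: 1 × 8
#>   area_um2 extension_um n_primary_branches voronoi_cv ln_signed_distance_um ...
#> 1  524128.        2235.                  7      0.121                -1258.
```

The gland covers ~0.52 mm², the leading edge sits 2.24 mm from the nipple,
7 primary branch points were found (matching the generator's 7 planted
bifurcations), their Voronoi territories are even (CV 0.12), and the leading
edge still trails the lymph-node centroid by 1.26 mm (negative sign).

```r
## proteomic screen: 3 groups x 5 samples, two planted 4-fold effects
eff <- list(list(3, c("wt4wk", "wt5wk"), 4),    # protein 3: 4x up in wt5wk
            list(8, c("wt4wk", "wt5wk"), 0.2))  # protein 8: 5x down in wt5wk
gen    <- generate_abundance_matrix(abundance_gen_params(n_proteins = 500,
                                    planted_effects = eff, seed = 2))
screen <- preprocess_abundance(gen$matrix)   # impute -> filter -> normalize
dd     <- differential(screen, "wt5wk", "wt4wk")
glance(dd)
#>   n_tested n_excluded n_significant n_unique alpha log2_cut q_method
#> 1      498          0            29        0  0.05        2 BH
dplyr::arrange(dd, p_value)[1:3, c("protein_id", "p_value", "q_value", "log2_ratio")]
#>   protein_0008 0.0000235  0.0117     -2.34
#>   protein_0003 0.000438   0.109       2.01
#>   protein_0033 0.00121    0.202      -0.427
```

Both planted proteins surface at the top with log2 ratios near ±2 (the
4-fold cut); `autoplot(dd)` draws the volcano plot.

```r
## protrusion dynamics and localized translation
tl <- generate_cyst_timelapse(cyst_gen_params(compartment_ratio = 1.8, n_frames = 8,
        protrusion_specs = list(list(length_px = 30, width_px = 8,
                                     birth_frame = 1, death_frame = 6)), seed = 5))
localized_translation_ratio(tl$frames[[2]], protrusion_id = 1)
#> 1.79
track_protrusions(tl$frames, frame_interval_h = 0.5)
#>   track_id first_frame last_frame n_frames lifetime_h max_length_um
#> 1        1           1          6        6          3          23.7
```

The painted 1.8 protrusion/body intensity ratio is recovered to 1.79, and a
protrusion alive from frame 1 to 6 at 0.5 h per frame has the expected 3 h
lifetime.

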