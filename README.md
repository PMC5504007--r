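# tilestitch

Automated microscopes image specimens larger than one field of view (FOV) by
acquiring a rectangular grid of partially overlapping tiles which must then be
stitched into a single mosaic. Naive stitching at the nominal overlap fails
because the mechanical stage is imperfect: the commanded 10 % overlap
fluctuates with the stage repeatability *r*, the actuators exhibit backlash,
and the camera axes are rotated by a small angle α relative to the stage axes.
Feature-poor tiles (sparse cell cultures, early time points) additionally
produce unreliable pairwise registrations.

`tilestitch` implements a stage-model-constrained stitching pipeline for such
grids, aimed at quantitative microscopy users who need positionally accurate
mosaics rather than merely seamless ones:

1. **Pairwise translations** between adjacent tiles via the Phase Correlation
   Method (PCM). The top *n* peaks (default 2) of the inverse-transformed
   normalized cross-power spectrum are each expanded into their four periodic
   interpretations `{(j, i), (j, i−H), (j−W, i), (j−W, i−H)}`, and the
   candidate with the highest normalized cross-correlation (ncc, the Pearson
   correlation of the implied overlap regions) wins.
2. **Stage-model estimation** from the translation tables H (west→east) and V
   (north→south): per-direction overlap (median of plausible displacements),
   camera angle α (pooled median of `atan2(−dy, dx)` over H pairs and
   `atan2(dx, dy)` over V pairs, inverting the observation model
   `(H_x, H_y) = (H cos α, −H sin α)`, `(V_x, V_y) = (V sin α, V cos α)`),
   repeatability *r* (robust half-range of displacement spreads), and a
   backlash tolerance check. User-supplied parameters bypass estimation.
3. **Translation optimization**: each line of H (column-wise) and V (row-wise)
   shares one true stage step up to ±2*r*, so entries deviating more than 4*r*
   from the line median are replaced by it; every translation is then refined
   by constrained hill climbing on the ncc surface, confined to the
   (4*r*)² window around its start.
4. **Mosaic assembly**: tiles and their ncc scores form an undirected grid
   graph; a weighted maximum spanning tree (edges consistent with the stage
   model boosted by +1) fixes each tile's position exactly once; overlay,
   average, or center-weighted linear blending renders the mosaic.
5. **Accuracy metrics** against reference ROI tables: Kabsch rigid alignment,
   Hungarian matching with a half-FOV deletion rule, centroid distance error
   `D_err = √((x_m−x_c)² + (y_m−y_c)²)`, signed area error
   `S_err = (A_c−A_m)/A_m × 100`, FP+FN counts, and blank-pixel counting.

A synthetic acquisition generator (`generate_source()`,
`simulate_acquisition()`) emulates the full stage model — nominal steps,
uniform jitter of magnitude *r*, camera-angle rotation, per-row backlash,
pixel noise, and a photobleaching stand-in — with exact ground truth, so every
stage of the pipeline is testable end to end.

## Worked example

```r
library(tilestitch)

src <- generate_source(seed = 7, width = 620, height = 620, content = "texture")
acq <- simulate_acquisition(src, rows = 4, cols = 4, tile_w = 128, tile_h = 128,
                            overlap_pct = 15, alpha_deg = 1, r_px = 2,
                            noise_sigma = 5, seed = 7)
res <- stitch_grid(acq$grid)
res
#> <stitch_result> 4 x 4 grid, mosaic 457 x 462 px
#> <stage_model> overlap H/V: 15.23%/14.84%  alpha: 1.042 deg  r: 4 px  backlash tol: 3%
#>   trusted: H=TRUE V=TRUE
```

The estimated stage model recovers the simulated conditions: overlap within
half a percentage point of the true 15 %, camera angle within 0.05° of the
true 1°, and a repeatability bound (4 px) that safely covers the true 2 px
jitter. `tidy()` returns the per-tile layout, `glance()` a one-row summary:

```r
head(tidy(res), 4)
#>     row   col     x     y edge_ncc file
#> 1     0     0     1     6   NA     tile_r0_c0
#> 2     0     1   107     2    0.951 tile_r0_c1
#> 3     0     2   215     4    0.960 tile_r0_c2
#> 4     0     3   324     0    0.967 tile_r0_c3
```

`x`, `y` are absolute pixel positions (minimum-normalized to 0); `edge_ncc`
is the correlation of the spanning-tree edge that placed the tile (`NA` for
the root). On this run all 16 tiles land exactly on the generator's
ground-truth positions. `render_mosaic(res$layout, acq$grid, "linear")`
produces the blended raster; `autoplot(res)` draws the tile layout colored by
edge quality; `evaluate_accuracy()` scores a stitched ROI table against a
reference.

A command-line front end with `stitch`, `apply` (re-use positions on another
channel), `simulate`, and `evaluate` subcommands is installed at
`inst/cli/tilestitch.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tilestitch.R", package = "tilestitch"))')" \
    stitch --dir tiles/ --pattern 'img_r{rr}_c{cc}.tif' --rows 5 --cols 5 --out stitched/
```

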