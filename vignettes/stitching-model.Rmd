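---
title: "Stage-model-constrained stitching: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-model-constrained stitching: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilestitch)
```

This vignette documents the model behind `tilestitch`, the parameters that
matter, the numerical choices made where the design was genuinely open, and
what the synthetic-data tests do and do not demonstrate about real data.

## The physical model

A motorized XY stage visits an $R \times C$ grid of commanded positions. Two
independent actuators move the sample, so the acquisition has four relevant
mechanical parameters:

* **Overlap** (percent of the tile extent): nominally user-chosen (e.g. 10 %),
  but the realized overlap fluctuates around it.
* **Stage repeatability** $r$ (px): the uncertainty of a single commanded
  position, $(x \pm r_x,\, y \pm r_y)$. A pairwise translation is a
  *difference* of two positions, so its error is bounded by $\pm 2r$ per axis
  — which is why every search window in the pipeline has side $4r$.
* **Camera angle** $\alpha$: the small rotation between stage axes and camera
  pixel axes. A horizontal stage step $H$ is observed by the camera as
  $(H\cos\alpha,\, -H\sin\alpha)$ and a vertical step $V$ as
  $(V\sin\alpha,\, V\cos\alpha)$.
* **Actuator backlash**: systematic error on direction reversal. It is treated
  as a *tolerance band* (default ±3 percentage points of overlap): an
  estimated overlap deviating from a user-declared nominal value by more than
  the band is deemed unreliable, the nominal value is kept, and $r$ is widened
  to `backlash_tol * extent / 100` so the optimizer can still reach the true
  offsets. Backlash is deliberately *not* modeled as a per-row additive
  correction; it only bounds what the pipeline is willing to trust.

Coordinates are 0-based pixels, $x$ rightward, $y$ downward. A translation
maps the first tile's origin to the second tile's origin, so a nominal 10 %
horizontal overlap on a $W$-px tile gives $dx \approx 0.9\,W$, $dy \approx 0$.

## Pairwise registration

`phase_correlation()` computes the inverse FFT of the normalized cross-power
spectrum. Numerical choices:

* The denominator is guarded as $\max(|F_a \bar F_b|,\ \varepsilon)$ with
  $\varepsilon = 10^{-12}\max|F_a \bar F_b|$, preventing blow-up at
  zero-magnitude frequencies.
* A spectrum that is zero everywhere except the DC term (constant tiles) is
  flagged degenerate and yields an invalid translation rather than an error.
* Images are promoted to double before the FFT; no window function is
  applied.
* Peak search masks a 3×3 wrap-around neighborhood after each selection, so
  the "top two peaks" are two distinct features rather than adjacent samples
  of one correlation lobe.

Each peak index $(i, j)$ is periodic-ambiguous and expands into four
displacement candidates $\{j, j-W\} \times \{i, i-H\}$. All
`n_peaks × 4` candidates are scored by `ncc()` — the Pearson correlation of
the two overlap regions implied by the displacement — and the best valid
score wins. Ties break by peak rank then candidate order, so results are
deterministic. An ncc is valid only when the overlap contains at least
`min_overlap_px` pixels (default: `max(25, 1 % of the tile area)`; smaller
overlaps produce statistically meaningless correlations) and both regions
have nonzero variance.

Some published implementations evaluate 16 sign/magnitude combinations per
peak; this package follows the four-interpretation reading, which suffices
because the ncc scoring is what disambiguates.

## Stage-model estimation

The estimation procedure is defined as robust statistics over the plausible
entries of the translation tables:

* **Selection**: an entry is plausible when its ncc is at least `ncc_min`
  (default 0.5) and its primary displacement lies in
  $[0.25 \cdot \text{extent},\ \text{extent})$. The lower band edge sits well
  below the nominal step so that at 50 % overlap — where the true step *is*
  half the extent — legitimately jittered entries are not rejected; 0.25
  still rejects gross failures (e.g. a $0.2\,W$ displacement among $0.9\,W$
  neighbors).
* **Overlap**: $100\,(1 - \mathrm{med}(d)/\text{extent})$ per direction.
* **Camera angle**: pooled median of per-pair angles (H pairs contribute
  $\mathrm{atan2}(-dy, dx)$, V pairs $\mathrm{atan2}(dx, dy)$).
* **Repeatability**: for each direction × axis, half the central 95 % span
  (2.5–97.5 percentile) of the selected displacements; $r$ is the ceiling of
  the largest of the four, floored at 1 px. The percentile half-range tracks
  the *bound* semantics of repeatability while ignoring the tails that the
  median/4r filter exists to repair. A single scalar
  $r = \max(r_x, r_y)$ is carried forward (the optimization window is
  square); per-axis values are kept as diagnostics.

Medians and percentiles were chosen over means and standard deviations
because the whole point of the estimation step is to survive the large
translation errors that feature-poor tiles produce. User-supplied parameters
are copied verbatim and never estimated. If neither direction yields a
plausible entry and no user values exist, stitching aborts ("cannot model
stage") rather than guessing.

## Translation optimization

Within one column of H all pairs share one commanded step, likewise per row
of V, up to $\pm 2r$; entries deviating from the line median by more than
$4r$ in either axis are replaced by the line's (median dx, median dy). The
rejected set is grown to a fixed point — deviants are dropped, the median
recomputed over survivors, deviation re-checked — which makes the filter
idempotent even when a line is mostly corrupted. Lines with no survivors take
the direction-wide survivor median; a direction with none at all takes the
model's nominal displacement. Repaired entries get their ncc invalidated and
recomputed at the repaired displacement before refinement, so the ascent
property below is well defined.

`hill_climb()` performs steepest-ascent over the integer lattice with
8-connected unit steps (all unvisited neighbors scored, best taken), lazy
memoized ncc evaluation, confinement to $|dx - dx_0| \le 2r$,
$|dy - dy_0| \le 2r$, and termination at a local maximum. Two invariants hold
by construction and are asserted in the test suite on every synthetic run:
the final ncc never falls below a valid starting ncc, and the result never
leaves the $(4r)^2$ window. On a unimodal window the climber provably equals
the exhaustive argmax (both are verified against a brute-force oracle); on a
multimodal window it may stop at the lesser mode — a documented limitation,
not a failure, since the window is small by design.

## Assembly

Each adjacent pair contributes one edge weighted by its optimized ncc. Edges
whose displacement lies within $4r$ per axis of the model's nominal
displacement get +1 added — since ncc ≤ 1, every model-consistent edge
strictly dominates every inconsistent one; invalid edges carry −10⁹ and are
used only if connectivity demands. The maximum spanning tree is extracted by
Kruskal's algorithm with a total tie-break order (weight, direction H before
V, row, col), making the tree — and hence the mosaic — deterministic.
Positions propagate from tile (0,0) along tree edges (forward adds
$(dx, dy)$, backward subtracts) and are min-normalized to 0.

Blending modes: `overlay` (last tile wins, row-major; the default — fastest,
and exact for all round-trip checks), `average`, and `linear` with per-tile
weight $w(u,v) = \frac{\min(u+1, W-u)}{\lceil W/2\rceil} \cdot
\frac{\min(v+1, H-v)}{\lceil H/2\rceil}$, which peaks at the tile center and
feathers seams. Accumulation is floating point with final clipping;
positions are integers throughout (no subpixel resampling), consistent with
an integer-resolution registration engine.

## Accuracy metrics

Reference-based scoring mirrors how microscope-side measurements are
compared with mosaic-derived ones: the computed centroids are rigidly aligned
onto the reference frame (Kabsch, proper rotation enforced via the
determinant correction of the SVD), matched by the Hungarian algorithm
(`clue::solve_LSAP`) on negative centroid distance (an ncc-of-patches
similarity is available when images are supplied), and any matched pair
farther apart than `max_dist` is unmatched, counting one FN and one FP. The
half-FOV rule (`max_dist` = half the smaller FOV dimension) is the default
convention; a whole-FOV threshold can be passed instead, as both conventions
appear in practice. Distance and area errors are
$D_{err} = \sqrt{(x_m-x_c)^2 + (y_m-y_c)^2}$ and
$S_{err} = (A_c - A_m)/A_m \times 100$. Blank pixels — zero-valued pixels
inside the union of placed tile rectangles — count stitching gaps; sources
generated by this package have minimum intensity 1 so that 0 unambiguously
means "never written".

## The synthetic generator

`simulate_acquisition()` reproduces the stage model exactly: nominal steps
$\text{extent} \times (1 - \text{overlap}/100)$, per-position uniform jitter
in $[-r, r]$ (uniform because repeatability is a bound, not a variance; a
truncated Gaussian option exists), optional backlash offset added to $x$ on
odd rows (serpentine reversal), rotation of stage positions by $\alpha$,
rounding to integer pixels, and tile extraction from a textured source.
Gaussian pixel noise and a multiplicative intensity decay on re-imaged
overlap strips (a deliberately crude photobleaching stand-in, present to
stress ncc rather than to model fluorophore kinetics) are optional.
$\alpha$ is applied to stage *positions*, not as an image rotation — valid in
the small-angle regime (≤ 5°) the model addresses, and required so that
integer ground truth exists for an integer-resolution stitcher.

The default texture is 1/f ("pink") noise, the standard spectral model of
natural images. This choice is load-bearing: phase correlation whitens the
spectrum, so a texture with no high-frequency content degenerates into
correlating per-tile noise. Pink noise keeps structure at all scales, as real
specimens do. The `blobs` content type (Poisson-placed Gaussian blobs with
recorded centroids and half-maximum areas) emulates sparse colony plates for
metric tests; `flat` exercises degenerate paths.

## Study conditions and problem sizes

The test suite and `scripts/acceptance.R` run 5×5 grids of 128×128-px tiles
at overlaps 10–50 %, $\alpha \in \{0, 1, 2\}°$, $r \in \{1, 2, 3\}$ px, pixel
noise 2 % of the intensity range — the documented operating envelope of the
stage model — plus 4×4 grids with 30 % of translations corrupted for the
repair filter. 128-px tiles keep the full pipeline subsecond per grid while
leaving every property scale-free; one caveat of the smaller tile is
quantization: 1 px is 0.78 percentage points of overlap at a 64-px step, so
overlap estimates are intrinsically coarser than they would be on
production-size (≈1000-px) tiles. Shift-recovery properties draw offsets the
way adjacent tiles produce them — a large primary displacement and a small
secondary one, either sign. Diagonal corner-to-corner offsets with under ~1 %
area overlap are *not* claimed: there the whitened spectrum's signal fraction
is comparable to its noise floor and the true peak can fall below the
two-peak default.

## What passing tests do and do not show

The generator shares the stitcher's geometric model, so the round-trip tests
certify the pipeline's internal consistency, the estimators' statistical
behavior under the declared perturbations, and exact agreement with
independent brute-force oracles (registration, hill climbing, spanning tree,
assignment, rigid alignment). They do not certify performance on real
specimens with flat-field shading, focus drift, periodic structures, or
content-free overlap regions — failure modes whose *symptoms* (wrong
translations) the corruption tests emulate, but whose *causes* they do not.
Very noisy real images may need pre-filtering before the registration step.

## Known limitations

* Full rectangular grids only; no missing tiles, no 3-D lattices.
* Integer-pixel registration; no subpixel peak interpolation.
* Single-start hill climbing; a multimodal ncc window within $4r$ of the
  start can trap it (bounded by the window size by construction).
* Backlash is a plausibility tolerance, not a correction term.
* Non-linear blending is out of scope; overlay/average/linear are provided.
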