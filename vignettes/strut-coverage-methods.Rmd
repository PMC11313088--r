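---
title: "Quantifying stent strut tissue coverage in intravascular OCT: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stent strut tissue coverage in intravascular OCT: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octcov)
```

## The problem

After a metallic coronary stent is implanted, a layer of neointimal tissue
gradually grows over its struts. The completeness and thickness of that
coverage is the imaging surrogate for vessel healing: struts that stay bare
are associated with stent thrombosis, and coverage status informs how long
dual antiplatelet therapy must continue. Intravascular optical coherence
tomography (OCT) is the only in-vivo modality with the micrometre-scale
resolution to assess coverage per strut, but manual frame-by-frame analysis
is slow enough that it is rarely done outside core labs.

`octcov` implements an automated per-frame analysis of stented OCT
cross-sections: it segments the lumen, detects metallic struts, measures the
neointimal thickness over each strut, and labels each strut covered or
uncovered. Because clinical OCT pullbacks are rarely shareable, the package
also ships a synthetic phantom generator that renders frames with exact
ground truth; the whole validation layer (PPV/TPR strut matching,
Bland-Altman agreement, thickness-distribution comparison) runs identically
against phantom truth or against external manual annotations.

## Image model and coordinate conventions

A frame is a Cartesian RGB cross-section with an isotropic calibration in
mm/pixel. All detection happens in polar coordinates: A-line `a` (of
`n_alines`, default 360 -- one per degree, enough to resolve the tens-of-µm
angular footprint of a strut at typical calibrations) points at angle
`theta_a = 2*pi*a/n_alines`, with A-line 0 at 3 o'clock and angles growing
counter-clockwise; depth `d` counts radial samples of `radial_step_px`
source pixels (default 1) from the catheter center. Resampling is bilinear
in both directions (nearest-neighbour is available for bit-exact tests).
Pixel coordinates are 0-based `(row, col)` with rows growing downward.

In OCT the lumen is dark (blood is flushed), the vessel wall is bright at
the lumen border and attenuates roughly exponentially with depth, and a
metallic strut reflects most of the incident light: it appears as a bright
bloom with a radially trailing shadow. Tissue covering a strut appears as a
bright band *anterior* to (shallower than) the bloom.

## Stage 1 -- overlay removal

Vendor exports stamp colored markers and text over the frame. Tissue in
these exports is near-gray, so the default mask targets saturated pixels
(`max(R,G,B) - min(R,G,B) > 60` on the 0-255 scale) and zero-fills them,
because overlays sit over the dark lumen or the outer field. Radial
inpainting (copy the nearest non-masked value walking inward along the ray)
is available per rule. The rule set is fully config-driven; the defaults are
a pragmatic choice, not a vendor specification.

## Stage 2 -- lumen segmentation

1. **Binarization.** Otsu's threshold (parameter-free and reproducible) on
   the polar grayscale. Scanning outward per A-line, the first
   above-threshold run of at least `min_run = 3` samples marks the lumen
   border; shorter runs are treated as isolated noise or catheter-sheath
   reflections. A-lines with no qualifying run (guidewire shadows) are
   filled by cyclic interpolation, consistent with how analysts trace
   through shadows. Note the border convention: bright pixels are *tissue*;
   the lumen is the dark region inside. The convention is recorded in the
   configuration (`lumen$border_convention`).
2. **Active contour.** The contour is parameterized as one radius per
   A-line -- a cyclic 1-D "snake" matching the star-shaped geometry of a
   lumen around the catheter, which keeps the energy well-posed. The energy
   is elasticity (`alpha = 0.1`) plus rigidity (`beta = 0.05`) minus
   `w_edge = 1.0` times the radial gradient magnitude (normalized to
   [0, 1]). Minimization is cyclic coordinate descent over a 3-coloring of
   the A-lines (indices `a`, `a±1`, `a±2` interact through the rigidity
   term, so every third index can move simultaneously with exact local
   energy deltas); moves are drawn from a small candidate set scaled by
   `gamma = 0.1` and accepted only if they lower the energy, so the energy
   trace is non-increasing by construction. Iteration stops when the mean
   absolute move per sweep drops below 0.05 px (or at `max_iter = 500`,
   with a warning). These weights were fixed on phantoms before the
   validation suites were run and are all config-exposed; the underlying
   publication record for such algorithms typically leaves them unstated.
3. **Morphological cleanup.** The enclosed polar region is rasterized,
   closed then opened with a disk (radius 2), components smaller than 20 px
   discarded, and the boundary re-extracted per A-line (the boundary lies
   between the last inside and first outside sample -- a half-pixel
   convention that keeps the radius unbiased); a cyclic running median then
   enforces a maximum adjacent-radius jump (15 px). Closing repairs narrow
   dropouts and opening shaves one-A-line spikes; the disk radius is the
   smallest that does so, because it also sets the smallest angular lumen
   feature the contour can represent -- a larger disk would round away
   genuine steps such as the bare side of a one-sided covered strut.

Lumen area is the shoelace area of the Cartesian-mapped polygon times the
squared calibration -- computed on the polygon, not by polar pixel
counting, to avoid angular-sampling bias.

## Stage 3 -- strut detection

1. **Ring mask.** Per A-line the wall mask extends from the lumen border to
   the depth where the smoothed signal falls below fraction `f = 0.1` of
   that A-line's peak wall intensity, clamped to [10, 80] samples; A-lines
   without wall signal clamp to the minimum. Because a strut's own shadow
   truncates exactly the A-lines the strut lives on, the per-line thickness
   is first inflated by a cyclic running maximum (window 9) -- the wall
   extent varies smoothly with angle, so narrow dips are shadow artifacts
   -- and then median-filtered (window 5).
2. **Shadow segmentation** on the red channel inside the mask, in fixed
   order: 3x3 median filter, Gaussian smoothing (sigma 1), adaptive
   threshold against the local mean (31x31 box; pixels *below* mean - 10
   are shadow -- shadows are dark, which fixes the polarity the wording
   "adaptive thresholding" leaves open), opening then closing with a disk
   of radius 1, connected components (8-connectivity, cyclic across the
   A-line seam). Components under 6 px are dropped; components spanning
   more than 20 A-lines are split at local width minima and each split is
   logged as a merge event -- two struts closer than about one shadow
   width are a documented failure mode of this class of algorithm.
3. **Profile criteria.** For each A-line of a component, the despeckled
   intensity profile from the lumen border through the mask is analyzed.
   Candidates are the strongest local maxima in decreasing order (a bloom
   under thick neointima can be dimmer than the tissue surface, so a
   global-maximum-only rule misses deep struts; the slope criteria decide
   instead). A candidate is accepted iff (a) it exceeds
   `baseline + k * spread` (`k = 3`), where baseline/spread are the
   median/MAD of the profile *outside* the candidate's own contiguous
   footprint, and (b) the profile drops below `drop_fraction = 0.25` of
   the peak within `drop_window_px = 15` samples behind it. Criterion (b)
   is what rejects bright tissue plateaus and calcification shadows
   without blooms.
4. **Localization.** A component yields a strut only when at least
   `min_hit_alines = 2` of its A-lines accept: an isolated single-line
   acceptance under speckle is overwhelmingly an artifact. Per accepting
   A-line the anterior edge is placed by
   walking from the peak toward the lumen on a median-of-3 filtered
   profile (which preserves ramps exactly) while the profile is strictly
   falling and at least 50% of the peak: the walk stops at the half-peak
   crossing or at the dip separating the bloom from the brighter tissue
   above it, and the edge is the boundary between the last two samples
   (half-pixel convention). Accepted peaks much deeper than the most
   anterior accepted peak of the same component (`ghost_margin_px = 10`)
   are discarded as ghost-strut artifacts. The strut position is the
   cyclic median of accepting A-lines; its anterior radius is the median
   of the accepted edges, so a single shadow-edge line that reads the
   neighbouring tissue surface cannot drag the strut position. At most one
   strut per A-line survives.

Speckle suppression for profile analysis is deliberately depth-wise only
(median of 3, then a 1-D Gaussian for the detection decisions), so
neighbouring struts are never smeared together angularly.

## Stage 4 -- coverage analysis

The stent contour interpolates anterior-edge radius over angle through the
strut midpoints with a periodic monotone cubic (Fritsch-Carlson on a
cyclically extended node set -- base R has no native periodic monotone
spline, and the one-period extension removes end effects). The contour is
only valid with at least 3 supporting struts spanning at least 180° of
arc; otherwise the stent area is reported as missing with a reason -- the
real failure mode when visible struts sit on a small part of the
circumference -- rather than thrown, so pullback summaries skip such
frames transparently.

Neointimal thickness per strut is the radial (along-A-line) distance from
the lumen contour to the strut's anterior edge -- the convention in
strut-level OCT analysis, and well-defined per strut -- clamped at zero
for protruding struts (negative tissue has no meaning; the side flags
decide such struts' labels).

Coverage is judged laterally, because the shadow hides tissue directly
behind the strut: on each side, over 3 A-lines just beyond the shadow
span, a side counts as covered when the median gap between the strut's
anterior radius and the lumen contour is at least `min_cover_px = 2`
radial pixels. Two pixels is the smallest gap distinguishable from the
half-pixel boundary conventions of the lumen and anterior-edge estimates
(a bare strut measures a one-pixel gap); the analysis resolves whole
pixels where an analyst resolves sub-pixel boundaries, so one-pixel
tissue layers read conservatively as uncovered. A strut is covered only when both sides are; tissue
on one side only, or none, labels it uncovered.

## The phantom generator

Phantoms are rendered natively in polar coordinates -- the generative
geometry is polar -- and the Cartesian frame is derived through the
package's own inverse transform, which doubles as a continuous regression
test of the transform pair. A phantom consists of:

* a lumen border given by a Fourier radius function
  `r(theta) = r0 + sum c_k cos(k theta + phi_k)` (up to 4 harmonics,
  amplitudes at most 15% of `r0`);
* a tissue band starting at the border with exponential depth falloff
  (default mean 180 gray at the border, decay constant 30 px);
* per strut: a coverage layer of stated thickness, a Gaussian bloom whose
  *50% leading edge* sits at `lumen radius + thickness` -- the anterior
  surface the detector estimates, so ground truth and estimate refer to
  the same physical boundary -- and a trailing shadow multiplying
  everything behind the bloom by an attenuation factor in [0, 0.2];
* multiplicative unit-mean gamma speckle (shape `L`, scale `1/L`; the
  standard coherent-imaging noise model; `L = 0` disables it, `L = 4` is
  the default noisy regime);
* optional guidewire shadow (an angular span attenuated over its full
  depth) and colored overlay marks in the image corners.

Ground-truth labels are assigned from the generating thickness -- covered
iff at least 1 px of tissue on both generated sides -- so classifier
accuracy is well-defined; one-sided coverage is emulated by locally
pushing the lumen border down to the strut plane on the uncovered side.
True areas come from the generating radius function (lumen) and from the
package's contour fit through the true strut positions (stent).

Randomized suites draw lumen size (`r0` 80-130 px), up to 3 harmonics,
6-10 struts with at least 8 A-lines separation, coverage thickness from
the strata {0, 3, 6, 12, 25} px (0-250 µm at the default 0.01 mm/px --
spanning bare metal through thick neointima at an early follow-up), bloom
sigma 1.6-2.2 px, bloom peak 230-255, shadow attenuation 0.05-0.15 and
shadow footprint 3-5 A-lines. The `hard` difficulty adds guidewire
shadows, overlay marks, 1-2 px (thin) coverage, a near-adjacent strut
pair, and one frame with struts confined to under 180° of arc.

What the phantoms deliberately do **not** model: catheter sheath rings,
side branches, thrombus, macrophages and calcifications (beyond a
bloom-free shadow used in tests), non-uniform rotation artifacts, or a
physically accurate wave simulation. Passing the phantom suites therefore
demonstrates the geometric and signal-processing correctness of the
pipeline under its own imaging model, not clinical-grade performance on
real pullbacks.

## Validation layer

Strut matching is greedy nearest-first one-to-one under Euclidean distance
with a 150 µm tolerance (about one strut-plus-bloom footprint; exposed in
config since published validations rarely state their criterion). Greedy
differs from optimal assignment only in pathological clusters; the test
suite carries a brute-force optimal-assignment oracle for small instances.
PPV = TP/(TP+FP) and TPR = TP/(TP+FN) return `NA` on empty denominators,
never errors. Bland-Altman agreement uses mean difference ±1.96 sample SD
(n-1) with Pearson correlation (`NA` for constant input), and thickness
distributions are compared with median/quartiles (linear-interpolation
type-7 convention) and a two-sided Mann-Whitney-Wilcoxon test
(`stats::wilcox.test`: exact for small untied samples, normal
approximation with tie correction otherwise).

## Problem sizes and numerical choices

The shipped test and acceptance suites use 50-frame suites at 360 A-lines
by up to ~300 depth samples per frame, which keeps a full run in the
minutes range on one core; the generator scales to arbitrary counts. Ties
at equal peak intensity break to the smallest depth (most anterior).
Degenerate inputs are first-class results, not crashes: blank frames are
per-frame segmentation failures recorded with their stage; empty strut
lists give an invalid stent contour with a reason; zero-radius contours
give zero area flagged degenerate. All randomness flows from explicit
seeds (the phantom generator saves and restores the global RNG state), and
the analysis itself is fully deterministic -- identical inputs and
configuration give byte-identical reports, which the acceptance suite
asserts.

## Known limitations

* Thin coverage near one pixel (10 µm at default calibration) sits at the
  resolution limit: the half-pixel edge convention classifies 1-2 px
  layers conservatively, mirroring the tendency of shadow-based pipelines
  to under-call thin neointima.
* Two struts closer than about one shadow footprint may merge into one
  component; the split heuristic flags these as merge events rather than
  guaranteeing separation.
* Overlapping (double-layer) stents, bioresorbable scaffolds, and
  malapposition distance are out of scope.
* Stent area depends on the interpolation rule through detected struts;
  with few or clustered struts it is reported as missing rather than
  extrapolated.
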