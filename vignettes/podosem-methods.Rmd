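---
title: "Methods: podocyte SEM morphometry in podosem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: podocyte SEM morphometry in podosem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`podosem` quantifies the podocyte filtration surface from calibrated SEM
images. The working objects are a `calibrated_image` (an intensity matrix
plus a µm/pixel scale), polygonal regions of interest and polyline profile
paths, detected `ridge_line`s, and per-image measurements that aggregate to
per-mouse values for group statistics. The internal coordinate convention
puts pixel centers at integer coordinates with the origin at the top-left
pixel center; ImageJ ROI coordinates (pixel-corner based) are shifted by
−0.5 on read and +0.5 on write. Rasterization uses the even-odd rule on
pixel centers with half-open edge intervals, so boundary pixels are
assigned deterministically and the result matches an exhaustive
point-in-polygon oracle exactly.

The pixel size of the original study's micrographs is not published (only
the magnification, 12,000×), so all physical-unit defaults are
configuration, never constants; every measurement carries its scale.

# Method 1 — SD fraction by Yen thresholding

The image is smoothed with a separable Gaussian (the "radius" parameter is
the Gaussian σ in pixels, matching the plugin the protocol names; default
2.00, reflect boundary, 4σ truncation), a 256-bin histogram is built from
the ROI pixels only, and Yen's maximum-correlation criterion is maximized
over every admissible split (both classes nonempty; ties broken toward the
lowest bin). Slit diaphragms are recessed grooves and image dark in
secondary-electron contrast, so the default polarity counts intensities at
or below the threshold as SD; the flag is exposed because the source
protocol never states it. Restricting the histogram to the ROI is likewise
a recorded decision: the fraction is defined over the ROI, and out-of-ROI
content would bias the threshold.

A property worth knowing: on realistic surfaces whose bright (foot-process)
mode is much heavier than the groove mode, Yen's criterion cuts close to
the bright mode, so the dark class includes the entire shoulder of each
groove. On synthetic surfaces this inflates the measured fraction by
roughly the transition-band area — a systematic overestimate of several
percentage points that grows with slit density. The implementation is
verified against an independent brute-force evaluation of the criterion;
the bias is a property of the criterion on such histograms, not of the
code. It is
consistent with this index's weak diagnostic performance in the study this
package operationalizes, and it is why the test suite checks Method 1
against an *analytic threshold oracle* (the fraction below the chosen
level) and for monotonicity in the true fraction, rather than for absolute
accuracy.

# Method 2 — SD fraction by Steger ridge detection

The detector follows the classic scheme:

1. **Derivatives.** Five Gaussian-derivative responses at scale σ
   (reflect boundary). Kernels are discretely normalized so a unit ramp has
   first derivative exactly 1 and `x²/2` has second derivative exactly 1;
   this makes the closed-form oracles in the tests exact to truncation
   error.
2. **Line points.** Per pixel, the Hessian's principal eigen-direction is
   the line normal; a pixel is a line point when the sub-pixel extremum of
   the second-order Taylor expansion along the normal falls within the
   pixel (|t| ≤ 0.5) and the signed curvature matches the polarity (dark
   lines: positive second derivative). Saliency is the scale-normalized
   magnitude σ²·|second directional derivative| of intensities normalized
   to [0, 1], so the published thresholds (0.00 / 0.17) are independent of
   source bit depth. The normalization is itself a recorded decision — the
   plugin's threshold scale is undocumented — and is re-tunable through
   `sweep_parameters()`.
3. **Linking.** Hysteresis: seeds are unused points with saliency ≥ upper
   threshold, visited in row-major order; lines extend through
   8-neighborhood points with saliency ≥ lower threshold, choosing the
   neighbor with the smallest orientation discontinuity (ties by sub-pixel
   distance), only in the forward half-plane. Lines shorter than the
   minimum length are discarded; maximum length 0 means unbounded; lines
   terminate rather than split at junctions. All tie-breaks are fixed, so
   identical inputs give bit-identical line sets.
4. **Widths.** Left/right edges are the gradient-magnitude maxima along
   the normal within `line_width/2` (0.25-px sampling, bilinear
   interpolation); a side with no interior maximum falls back to the cap.
   No bias correction is applied, so for grooves much narrower than the
   effective smoothing the measured width approaches
   2·√(s² + σ_eff²) rather than the true width — the well-known
   smoothing bias of gradient-extrema edges.
5. **SD binary.** Default `line-envelope` mode: the detected dark lines
   *are* the slits, and the mask is the per-point width envelope swept
   along each centerline (pixel-center-inside convention, matching the ROI
   rasterizer). An `inter-ridge` mode (fill between paired adjacent
   centerlines whose mutual normal distance is at most `line_width`) is
   also provided, because the figure caption describing the original
   binary admits that reading. Both modes intersect the ROI.

**Parameter profiles.** The published profile (blur 4.00, σ 5.70, line
width 15, thresholds 0.00/0.17, min length 5, max length 0) is the package
default (`ridge_params()`, `default_config("published")`) — it is the
citable baseline, tuned by the original authors on their own training
images at their (unpublished) pixel scale. Detection scale and width cap
are physical lengths, so for the simulator's geometry they must track the
pixel size. `simulated_ridge_params(scale)` fixes them as physical lengths
— detection scale 0.05 µm, width cap 0.2 µm, seeding threshold 0.17 —
selected once by the same procedure the study used: a ground-truthed
`sweep_parameters()` ranking (sensitivity − false-positive rate) on
noiseless training patterns, then frozen. The test suite demonstrates the
selection: in a σ grid spanning 1.5–12 px on an image whose slit
half-width is 7.5 px, the matched scale ranks first.

The width-match analysis behind that choice: for the simulator's groove
profile the gradient extrema of the observed (blurred) profile sit near
the true slit edge when the total smoothing σ_eff = √(blur² + σ²) is
comparable to the slit half-width. At 0.01 µm/px the slit is 15 px wide,
and blur 4 + σ 5 gives σ_eff ≈ 6.4 px — measured widths within ~1 px of
truth across the 20–40% sweep. With a σ far from the structure scale the
envelope systematically over- or under-covers; that is precisely why the
original protocol optimized its parameters on training images rather than
using defaults.

# Method 3 — FPW by plot profile

Intensities are sampled by bilinear interpolation at uniform arc-length
steps (default 1 px) along an annotated polyline; arc length is converted
to µm by the calibration. Peaks are interior local maxima with topographic
prominence ≥ `min_prominence` × dynamic range and pairwise separation ≥
`min_separation` (greedy from the most prominent), refined by parabolic
interpolation of the 3-point neighborhood. The peak criterion is not
stated in the source protocol, so both parameters are recorded,
config-exposed decisions: prominence 0.2 for clean profiles (it passes the
synthetic-grating suite exactly), 0.35 in the cohort pipeline default
because membrane-texture bumps on realistic surfaces reach ~20–25% of the
dynamic range. Bright crests (polarity `"bright"`) define FP centers; a
trough flag is provided. Per-profile FPW is the mean adjacent peak
spacing; the per-glomerulus value is the unweighted mean over the 3–5
profiles, excluding (with a warning) profiles with fewer than two peaks.

The obliquity property is verified rather than corrected: sampling at
angle θ to the grating normal inflates FPW by 1/cos θ (checked at 0°, 30°,
45°), which documents why this method is sensitive to sectioning and
annotation orientation.

# The simulator

`make_pattern()` draws bright quasi-parallel FP ridges separated by dark
slit grooves on a calibrated grid:

- **Geometry.** Foot-process period `fp_period` (µm) and slit width
  `slit_width` (µm) define the true SD fraction `slit_width / fp_period`.
  The reference pattern is 500×500 px at 0.005 µm/px (period 0.50 µm =
  100 px, slit 0.15 µm, true fraction exactly 30% by construction: the
  image width is a whole number of periods and slit edges fall between
  pixel samples). A lateral `phase` offset (fraction of a period) lets
  cohorts randomize slit positions so ROI cropping samples them without
  bias. Optional sinusoidal warp (`curvature`, px) bends the slits;
  `orientation` rotates the pattern.
- **Cross-profile.** Grooves are smoothed trapezoids — plateau half-width
  0.85 and Gaussian shoulder 0.15 of the groove half-width — so edge
  operators see realistic gradients rather than hard steps. The slit mask
  (ground truth) is |offset| ≤ half-width, captured before any noise.
- **Topographic shading.** Secondary-electron yield rises with surface
  tilt, so convex FP tops image brighter than their flanks: a
  raised-cosine dome spans each FP (`fp_relief`, default 0.15 of unit
  range), putting crests at `background` (0.9) and slit-adjacent flanks
  0.15 lower. The groove floor sits `slit_depth` (0.65) below the flanks.
  The domes are what give plot profiles genuine FP peaks.
- **Texture and noise.** Correlated membrane texture (Gaussian field,
  correlation length 3 px, SD 0.08, damped inside grooves) broadens the
  bright intensity mode the way real membrane roughness does; additive
  Gaussian noise (SD 0.03 of unit range) and optional multiplicative
  speckle and a linear illumination ramp are applied after the truth is
  captured. All randomness is deterministic under the pattern seed, and
  the generator restores the caller's RNG state.

`simulate_cohort()` reproduces the study design: 17 non-diabetic vs 15
diabetic mice, 4 images (glomeruli) per mouse (the protocol used 3–5),
per-mouse true SD fraction ~ Normal(group mean, between-mouse SD) with the
published moments (32.00 ± 2.08% vs 29.82 ± 1.98%), per-image fraction ~
Normal(mouse value, within-mouse SD 1.0 — a chosen realistic default, not
a published value), both truncated to (5, 60)%. Each image's FP *period*
is back-solved from its sampled fraction at fixed slit width: effacement
widens foot processes while slit geometry stays constant, so a lower SD
fraction also means a larger FPW, giving Method 3 a genuine group signal.
Mouse-level fasting glucose and albumin-to-creatinine ratio are emitted
with group offsets and a negative dependence on the true fraction,
emulating diabetic stress markers for the correlation layer. Cohort images
default to 400×400 px at 0.01 µm/px so a region of interest holds several
slits (limiting slit-count quantization of the per-image truth) while a
whole-cohort analysis stays fast.

**What the simulator does not emulate:** electron-optical physics
(charging, edge brightness halos, detector shot statistics), 3-D
topography and perspective foreshortening, curved glomerular surfaces,
heterogeneous effacement within one image, and annotation error in ROI or
profile placement. Passing tests therefore demonstrate correctness of the
measurement and statistics pipeline on controlled geometry, not
performance on real micrographs.

# Numerical choices and degenerate inputs

- Blur/derivative boundary: reflection with the edge included; constants
  are preserved and interior mass conserved to 1e−9 relative.
- Yen: candidate thresholds restricted to splits with two nonempty
  classes; degenerate (single-bin) histograms raise an error; near-flat
  criteria are resolved toward the lowest bin.
- Hessian eigenvectors fall back to the coordinate axes for exactly
  diagonal Hessians; line-point sub-pixel offsets are clamped to |t| ≤ 0.5.
- Envelope rasterization keeps pixels only when the pixel *center* lies
  inside the width band, matching the ROI rasterizer's convention (an
  any-overlap rule would dilate every slit by about one pixel and bias the
  fraction upward in proportion to slit density).
- Flat profiles (no dynamic range) and polylines shorter than two sampling
  steps are errors; profiles with fewer than two peaks are excluded from
  FPW with a warning, and an all-excluded glomerulus is an error.
- Groups with fewer than two mice yield summaries only, with a warning;
  tests and ROC are skipped.
- RoiSet archives are written as stored (uncompressed) ZIP entries with a
  table-driven CRC-32, so the package has no archive-tool dependency.

# Problem sizes in the shipped tests and acceptance script

Unit and property tests run on patterns between 60² and 500² px. The
calibration sweep uses five 400² patterns at true fractions 20–40%; the
end-to-end cohort test and the acceptance script analyze one full
32-mouse, 128-image cohort at 400² px — about two minutes on one CPU.
These sizes are the package's validation defaults; all generators accept
larger images and more replicates.

# Known limitations

- Width estimation carries the gradient-extrema smoothing bias (no
  Steger-style bias correction); accurate fractions require detection
  parameters matched to the image scale, as discussed above.
- Yen thresholding systematically includes groove shoulders on surfaces
  with a dominant bright mode; Method 1 is best treated as a relative,
  not absolute, index.
- FPW depends on profile orientation as 1/cos θ and on the peak criterion
  for irregular or double crests.
- The hierarchical image-within-mouse structure is handled by per-mouse
  averaging (as in the source protocol), not by mixed-effects modeling.
- The study's printed upper confidence limits for sensitivity/specificity
  match neither the Wilson nor the Clopper–Pearson interval; only the
  lower limits (which match Wilson exactly) are reproduced and tested.
- The Hedges' g interval is the normal-approximation interval computed on
  the uncorrected d and then scaled by the small-sample factor (this
  reproduces the printed limits); the common alternative computed directly
  on g is available behind `ci_on = "g"`.
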