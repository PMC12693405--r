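# podosem

Quantitative podocyte ultrastructure morphometry from scanning electron
micrographs (SEM).

Podocytes wrap the glomerular capillaries with interdigitating foot
processes (FPs); the narrow grooves between adjacent FPs are bridged by the
slit diaphragm (SD), the final sieve of the kidney filtration barrier.
Early diabetic injury flattens and widens foot processes (effacement),
shrinking the slit area long before classical histology shows damage.
`podosem` implements three complementary read-outs of this geometry for
calibrated SEM surface views, plus the statistical layer needed to evaluate
them as diagnostic indices:

1. **SD fraction by thresholding** — Gaussian blur (σ = 2 px), automatic
   Yen histogram threshold inside a polygonal region of interest (ROI),
   SD% = 100·(slit-side pixels)/(ROI pixels).
2. **SD fraction by ridge detection** — Steger's curvilinear detector
   (Gaussian-derivative Hessian eigen-analysis, sub-pixel line points,
   hysteresis linking, per-point width from gradient-magnitude extrema)
   applied to the dark slit grooves; the SD binary is the width envelope of
   the detected centerlines. Defaults follow the published parameter
   profile: blur σ = 4, detector σ = 5.70, line width 15 px, saliency
   thresholds 0.00/0.17, minimum line length 5 px.
3. **Foot-process width (FPW) by plot profile** — bilinear intensity
   profiles along annotated polylines drawn across multiple FPs; FPW is the
   mean spacing of adjacent intensity peaks (µm).

A synthetic SEM simulator (`make_pattern()`, `simulate_cohort()`) generates
interdigitated FP/slit surfaces with exact ground truth (slit mask, true
SD%, true FPW), hierarchical mouse/image structure, and diabetic-versus-
control group effects, so the whole pipeline is testable end to end without
micrographs. The diagnostics layer covers per-mouse aggregation, pooled
t-tests, Hedges' *g* with small-sample correction, empirical ROC/AUC with
the Youden-optimal cutoff, Wilson score intervals, Pearson correlation,
simple regression, and Bland–Altman agreement.

## Worked example

```r
library(podosem)

# a full synthetic study: 17 control vs 15 diabetic mice, 4 images each
cohort <- simulate_cohort(cohort_spec(seed = 1))
res <- run_study(cohort, methods = "ridge",
                 config = default_config("simulated"))
res$reports$ridge
```

```
non-DN   n=17  mean 35.91 +- 2.38  95% CI [34.69, 37.13]
STZ-DN   n=15  mean 32.24 +- 2.24  95% CI [31.00, 33.48]
t = 4.466 (df 30.0), p = 0.0001027
Hedges' g = 1.54, 95% CI [0.74, 2.35]
AUC = 0.8902; Youden J = 0.70 at threshold 33.61
sensitivity 80% [54.81, 92.95]%, specificity 88% [65.66, 97.91]%
correlation with fasting_glucose: R = -0.67 (n = 32, p = 2.305e-05)
correlation with acr: R = -0.74 (n = 32, p = 1.472e-06)
```

The ridge-detected SD fraction separates the groups (lower SD% in the
diabetic group, large effect size, AUC ≈ 0.89) and correlates negatively
with the simulated diabetic stress markers — the qualitative behavior
reported for this index on real micrographs.

Single images work the same way:

```r
pat <- make_pattern(pattern_spec(seed = 2))     # synthetic surface + truth
roi <- full_roi(pat$image, margin = 25)
sd_fraction_by_ridge(pat$image, roi, params = simulated_ridge_params(0.005))
sd_fraction_by_threshold(pat$image, roi)
```

Real data enter through `load_image()` (calibrated TIFF) and `read_rois()`
(ImageJ `.roi` / `RoiSet.zip` / plain-text polygons). A thin command-line
front end with `simulate`, `measure`, `stats`, `compare`, and `sweep`
subcommands is installed at `inst/cli/podosem.R`.

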