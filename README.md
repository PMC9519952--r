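# tissueqc

Non-destructive quality assessment of tissue-engineered constructs from
fluorescence lifetime imaging (FLIm) and high-frequency ultrasound
backscatter microscopy (UBM), in R.

Engineered tissues — the motivating system is scaffold-free self-assembled
articular cartilage — are normally characterized by destructive assays:
biochemistry for collagen and glycosaminoglycan content, stress-relaxation
and tensile tests for mechanics, histology for structure. A sample that has
been tested is a sample that cannot be implanted. `tissueqc` implements the
analysis side of a label-free alternative: per-channel FLIm average-lifetime
maps report surface biochemistry, reconstructed UBM B-mode stacks report
internal structure and voids, and the two are fused into a single
homogeneity index

    HI = 1/2 (HS + 1/2 [HF2 + HF3]),      HS = 100 − void volume (%)

where HF2/HF3 are the areas (in %) under the lifetime PDF of channels 2 and
3 within ±0.1× the mean lifetime. A perfectly homogeneous sample scores
100%. Linear calibrations and Lin's concordance correlation coefficient
ρc = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²) tie the optical measurements to
destructive reference values.

The package covers, module by module:

* **FLIm** — background subtraction, intensity-weighted average-lifetime
  (temporal centroid) estimation, per-channel lifetime maps with low-signal
  masking, circular-ROI statistics, optional Richardson–Lucy IRF
  deconvolution.
* **UBM** — zero-phase 20–60 MHz Butterworth filtering, analytic-signal
  envelope, depth conversion, bilinear resampling to 5 × 5 µm, 8-bit log
  compression at 60 dB.
* **Void volumetry** — speckle-reducing anisotropic diffusion (SRAD, Rcpp),
  Otsu total-sample segmentation with hole filling, two-pass adaptive void
  thresholding on the decompressed amplitude scale, shape-based
  (distance-transform) mask interpolation across frames (factor 20), voxel
  counting.
* **Homogeneity** — HS, HF2, HF3 and the combined HI.
* **Mechanics** — a biphasic (porous-elastic) series solution for unconfined
  ramp–hold stress relaxation, derived in-package and cross-checked against
  a finite-difference oracle; Levenberg–Marquardt parameter recovery
  (E, ν, k); tensile Young's modulus from the auto-selected linear region.
* **Calibration** — OLS calibrations (per treatment group and pooled),
  extrapolation-flagged predictions, leave-one-out cross-validation, Lin's
  concordance.
* **Synthetic data** — seeded FLIm rasters, speckle RF phantoms with
  ellipsoidal voids of exact analytic volume, stress-relaxation records,
  and linked optical/destructive datasets, each with ground truth.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and every
result type has an `autoplot()` method.

## Worked example

```r
library(tissueqc)

# --- ultrasound: phantom with a known 8% void fraction, end to end
phantom <- gen_rf_phantom(rf_phantom_with_void(8, seed = 42))
bmode   <- reconstruct_volume(phantom$volume)
bmode
#> <bmode_volume> 9 frames of 203 x 320 px | voxel 5 x 5 x 200 um, DR 60 dB
voids <- void_volumetry(bmode)
voids
#> # A tibble: 1 × 3
#>   total_mm3 void_mm3 void_percent
#>       <dbl>    <dbl>        <dbl>
#> 1      1.48    0.113         7.64

# --- FLIm: two-channel raster with a brighter-lifetime patch
flim <- gen_flim_phantom(flim_phantom_spec(
  base_lifetime = c(ch2 = 4.5, ch3 = 4.0),
  patches = list(list(center = c(15, 15), radius = 7, lifetime = 4.8)),
  noise = "poisson", seed = 42))
maps <- build_lifetime_map(flim$decays)
roi_statistics(maps$ch3)
#> # A tibble: 1 × 7
#>   channel mean_lt sd_lt n_pixels center_row center_col radius
#>     <int>   <dbl> <dbl>    <int>      <int>      <int>  <dbl>
#> 1       3    4.11 0.271     1069         24         24   18.4

# --- combined homogeneity index
homogeneity_result(maps$ch2, maps$ch3, voids$void_percent,
                   sample_id = "demo", day = 28)
#>   sample_id day    hs hf2   hf3    hi
#> 1      demo  28 92.36 100 88.21 93.23
```

The sample loses structural homogeneity to its 7.6% void volume
(HS = 92.4) and biochemical homogeneity to the lifetime patch, which puts
11.8% of CH3 pixels outside the ±10% window (HF3 = 88.2); CH2, spatially
uniform up to shot noise, stays at 100. The combined index is 93.2%.

```r
# --- calibrating an optical predictor against a destructive reference
linked <- gen_linked_dataset(seed = 42)
calibrate(linked$samples, pairs = "ch3_lt:compressive_modulus")[, 1:8]
#>   predictor            response  group slope intercept r_squared   n  p_value
#> 1    ch3_lt compressive_modulus pooled   156      -273     0.629 192 8.67e-43
```

The fitted slope of 156 kPa/ns recovers the generating link (150 kPa/ns)
from 192 noisy construct-timepoints with R² = 0.63.

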