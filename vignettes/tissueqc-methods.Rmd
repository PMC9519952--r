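---
title: "Methods: non-destructive quality metrics for engineered tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-destructive quality metrics for engineered tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueqc)
```

Tissue-engineered constructs (the motivating system is scaffold-free,
self-assembled articular cartilage grown from chondrocytes) must be
characterized before use, but the reference assays — biochemistry,
mechanical testing, histology — destroy the sample. `tissueqc` implements an
analysis pipeline for two label-free imaging modalities that leave the
sample intact: fluorescence lifetime imaging (FLIm), whose per-channel
average lifetimes track matrix composition at the surface, and
high-frequency ultrasound backscatter microscopy (UBM), which resolves
internal structure and voids through the sample depth. The two are combined
into a single homogeneity index, and linear calibrations plus Lin's
concordance correlation link the optical readouts to destructive reference
values. Raw FLIm and UBM instrument recordings are rarely available for
method development, so every stage ships with a seeded synthetic phantom
generator carrying exact ground truth; all quantitative claims in the
package are established against those phantoms by the test suite.

## Fluorescence lifetime maps

A raster scan delivers, per 20 µm pixel and per spectral channel
(CH1 375–410, CH2 450–485, CH3 532–565, CH4 595–660 nm), a fluorescence
decay sampled every 80 ps. The per-pixel statistic is the
*intensity-weighted average lifetime*: the temporal centroid of the
background-subtracted decay measured from its onset,

$$\bar\tau = \frac{\sum_k (t_k - t_{\mathrm{onset}})\, I_k}{\sum_k I_k} + \tfrac{dt}{2}.$$

Numerical conventions, each chosen for determinism:

* **Background** is the mean over a pre-trigger sample window; negative
  post-subtraction samples are clipped to zero only when the centroid sums
  are formed, keeping the estimator non-negative.
* **Onset** is the argmax of a 3-sample moving average (a threshold policy
  is available). The moving average makes the argmax robust to single-sample
  noise spikes.
* **Half-sample correction.** Samples are treated as bin centers of width
  `dt`. The plain discrete centroid of a sampled exponential is biased by
  −dt/2 (−1.3% for τ = 3 ns at 80 ps); adding dt/2 removes this to O(dt²).
  This is part of the estimator definition, not a calibration.
* **Low signal.** A pixel is missing when its total post-clip intensity
  falls below 50× the per-pixel background standard deviation (estimated
  from the pre-trigger window). This threshold is configurable; 50× makes
  centroids of surviving pixels stable to well under a percent.
* **Instrument response.** The centroid needs no deconvolution for IRFs
  much narrower than the lifetime (a Gaussian IRF shifts both peak and mass
  so the centroid from the peak is nearly unchanged). For measurably broad
  IRFs an opt-in Richardson–Lucy deconvolution (`deconvolve_irf()`) is
  provided as preprocessing.

ROI statistics use the *population* standard deviation (divide by n): the
ROI's pixels are the full population of interest, not a sample from it. No
single ROI radius is canonical for such scans, so the default ROI is the
largest circle inscribed in the valid-pixel region; center and radius are
user-configurable and reported in the output.

## B-mode reconstruction

Raw RF frames (A-lines sampled at 400 MHz, frames every 200 µm) are turned
into 8-bit B-mode images by band-pass filtering 20–60 MHz, envelope
detection, depth conversion, interpolation to 5 × 5 µm pixels, and log
compression at 60 dB dynamic range:

* The band-pass is a 4th-order Butterworth applied with zero phase
  (forward–backward, i.e. the squared-magnitude response), implemented in
  the frequency domain simultaneously for all lines of a frame. Zero phase
  preserves echo depth registration.
* The envelope is the analytic-signal magnitude along the axial axis.
* Depth uses a sound speed of 1540 m/s (configurable); the axial sample
  pitch is then c/(2 fs) ≈ 1.9 µm, resampled bilinearly to 5 µm.
* Log compression maps the per-frame envelope maximum to 255 and −60 dB to
  0, rounding half-up for cross-platform determinism. A volume-wide
  normalization flag exists for intensity-comparable frames.

The chain is deterministic: identical input and configuration give
bit-identical output, which the tests assert.

## Void segmentation and volumetry

Three observations drive the design:

1. **Speckle must be suppressed before thresholding.** Speckle-reducing
   anisotropic diffusion (SRAD) is used, with the diffusion stopped by the
   local instantaneous coefficient of variation. The speckle scale `q0` is
   estimated from the bright (above-median) pixels — the speckle inside the
   tissue — and held constant over iterations; the default 30 iterations at
   step 0.7 (the explicit scheme is stable up to step 1) reduce interior
   variance by more than half while keeping most of the boundary gradient,
   which the tests verify on phantoms.
2. **Thresholds belong on the linear amplitude scale.** Log compression
   stretches the dark side of every blurred edge, so a histogram threshold
   on the 8-bit image lands well outside the true boundary. Both
   segmentations therefore invert the log compression internally and
   threshold the relative envelope amplitude, where the boundary of a
   blurred object passes through the half-amplitude contour — the unbiased
   edge position. Otsu's method on this scale separates tissue from
   background essentially at half amplitude.
3. **A void's own darkness must not define its reference.** The void
   threshold is two-pass: pass 1 marks pixels below half the plain local
   Gaussian-weighted mean (window 51 px = 255 µm) and hole-fills them; pass
   2 recomputes the local mean over tissue only, excluding a dilated shell
   around the provisional voids (the partial-volume mix zone at an edge is
   neither void nor clean tissue), and rethresholds at half the local
   *tissue* level. Candidates are restricted to the total mask eroded by
   3 px — the sample's outer boundary layer sits at half amplitude by
   construction and must not count as void — hole-filled, and filtered by a
   100 px (0.0025 mm²) minimum area.

The total-sample mask takes the largest connected Otsu foreground
component (one construct per scan), closes it morphologically (radius 4 px)
to bridge speckle notches in thin tissue bands, flood-fills interior holes
so voids count toward total volume, and finally fills each axial column
between its first and last tissue pixel. The last step encodes the
assumption that a construct cross-section is star-convex along depth; it
guarantees interior voids stay enclosed even where a notch breaches a thin
band. Contrast-limited adaptive histogram equalization is available ahead
of the void threshold (`contrast = "clahe"`, EBImage's parameterization)
but is off by default: remapping amplitudes moves the detected boundary off
the half-amplitude contour.

Masks are interpolated across frames shape-wise — linear interpolation of
signed Euclidean distance transforms, thresholded at zero, factor 20 —
which reproduces the original frames exactly at their positions and turns
n frames into (n−1)·20+1 slices. A frame adjacent to an empty frame tapers
out as a cone: the empty side is represented by a constant level set at
minus the shape's largest inside distance, so the shape vanishes halfway
through the gap. This is the natural boundary condition for a shape that
ends between frames; it slightly mis-estimates curved caps, a limitation
shared by any shape-based interpolation at 200 µm frame spacing. Volumes
are voxel counts times the post-interpolation voxel volume
(5 × 5 × frame-spacing/20 µm³), and
`void % = 100 · void volume / total volume`.

## Homogeneity index

Structural homogeneity is `HS = 100 − void %`. Biochemical homogeneity per
FLIm channel is the area under the probability density function of the
per-pixel lifetimes within ±0.1× the mean lifetime, as a percentage — for
the default empirical distribution this is exactly the fraction of pixels
in the closed window, so a window covering the whole observed range gives
exactly 100. A Gaussian-kernel density option (Silverman bandwidth) exists
for sensitivity checks; the empirical reading is the default because it is
the unique assumption-free interpretation. The mean is taken over all valid
pixels of the map rather than a sub-ROI: homogeneity is a whole-sample
property. The combined index is

$$HI = \tfrac12\left(HS + \tfrac12\,[HF2 + HF3]\right),$$

an equal-weight combination of structural and (averaged) biochemical
homogeneity; a perfectly homogeneous sample scores 100%.

## Biphasic and tensile mechanics

Unconfined stress relaxation of a cylindrical disk between frictionless
impermeable platens is modeled with linear biphasic (porous-elastic)
theory: the generic "biphasic theory" label is interpreted as the classical
radial-fluid-exudation problem because that is the boundary-value problem
of the unconfined test. The solution was derived in-package via Laplace
transform; stress relaxation modes are set by the roots of

$$J_1(\alpha) = \beta\,\alpha\,J_0(\alpha), \qquad \beta = \frac{1-\nu}{1-2\nu},$$

with decay rates $\alpha_n^2 H_A k / a^2$ and amplitudes
$2\mu\beta/(\beta^2\alpha_n^2 + 1 - 2\beta)$; the equilibrium stress is
$E\,\varepsilon_0$ and the instantaneous response $3\mu\,\varepsilon_0$
(incompressible limit), identities used as internal checks. Ramp–hold
loading is handled by exact Duhamel superposition of the step response, so
no numerical convolution is involved. Fifty series terms are kept with a
tail check on the ramp-response amplitudes (which fall off like $n^{-4}$).
The tests cross-validate the series against an independent Crank–Nicolson
finite-difference solution of the radial PDE to within 1%.

Fitting uses Levenberg–Marquardt least squares on transformed parameters —
log E, log k, logit(ν/0.5) — which enforces E, k > 0 and 0 ≤ ν < 0.5
without constrained optimization, from five deterministic starts (a
heuristic E from the plateau, a permeability scale from the relaxation
1/e-time, and a fixed design over ν and k multipliers). Records that do not
reach their relaxation plateau (final-decile drift above 5% of the
relaxation amplitude) are flagged low-confidence. All three parameters are
fitted by default; `fix_nu` reproduces the common practice of pinning the
Poisson ratio. Stress is engineering stress (force over initial area).

Tensile Young's modulus is the ordinary least-squares slope over the linear
portion of the stress–strain curve. In automatic mode the contiguous window
of at least 30% of the pre-failure points (failure = stress peak)
maximizing R² is selected; if no window reaches R² = 0.9 a linearity error
is raised rather than returning a meaningless slope.

## Calibration and concordance

Optical–destructive relationships are simple linear least squares fits; R²
is the squared Pearson correlation, and p-values are reported raw (no
multiple-testing correction, matching how such calibration panels are
usually reported; the output makes this explicit). When a treatment column
is present, fits are stratified per treatment with a pooled fit alongside,
mirroring a matched-sample design where correlations are modeled per group.
Missing values are deleted pairwise-complete and the dropped count is
reported. Predictions outside the training range are flagged as
extrapolations, and `calibration_loocv()` provides leave-one-out
predictions for out-of-sample agreement assessment — whether a calibration
is trained on all samples or cross-validated is left to the analyst, since
either reading is defensible.

Lin's concordance correlation coefficient is computed with population
(divide-by-n) moments, as in its original formulation:

$$\rho_c = \frac{2\,s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}.$$

The sample/population distinction cancels everywhere except against the
mean-shift term, which is why the convention must be fixed; tests assert
the closed-form values and the bound $|\rho_c| \le |r|$.

## Synthetic phantoms: what they emulate, and what they do not

All generators are pure functions of their specification, seed included;
each draws from its own labelled substream of the user seed so adding a
generator never perturbs another's output.

**FLIm phantoms** place a disk-shaped sample (plus optional circular
patches of altered lifetime) in a zero-signal background and synthesize
mono-exponential decays (a bi-exponential option supports estimator-bias
studies) convolved with a Gaussian IRF (100 ps FWHM default) via the exact
exponentially-modified-Gaussian expression, at 80 ps sampling. Poisson or
Gaussian noise is optional; the default photon background is zero, as in
dark-count-free time-resolved photon counting — a nonzero Poisson baseline
interacts with negative-clipping to bias long-window centroids, which is an
estimator property worth studying deliberately rather than a default.

**RF phantoms** fill a rectangular tissue slab (1.3 × 1.6 × 0.7 mm inside a
1.6 × 1.6 × 1.0 mm scanned extent; the slab models the interior of a
construct) with uniformly placed scatterers at 60 000/mm³ — at least ten
per resolution cell, i.e. fully developed speckle, which the tests confirm
via the Rayleigh envelope SNR of 1.91 — weighted by Gaussian lateral and
elevational beam profiles (σ = 30 µm, matching the ~55 µm FWHM focal width
of an f/1.5, 42 MHz transducer), convolved axially with a Gabor pulse
(42 MHz, 40% fractional bandwidth), and overlaid with receiver noise.
Scatterer placement does not depend on the void list (voids only remove
scatterers), so growing a void with a fixed seed changes nothing else.
Voids are ellipsoids; the convenience constructor `rf_phantom_with_void()`
sizes a single sphere/oblate for fractions up to ~5% and a single
elevation-elongated cleft — the shape of real matrix clefts — for larger
fractions, always leaving a generous tissue ring to the slab faces, because
a tissue band thinner than the blur merges a void with the background in
the reconstructed image (as it would in a real scan).

Not emulated: frequency-dependent attenuation, depth-dependent focusing
and gain, multiple scattering, refraction, elastic anisotropy, realistic
biochemical gradients, or instrument drift. Passing the phantom suite
therefore demonstrates the correctness of the reconstruction and
measurement chain under ideal acoustics, not robustness to every artifact
of real instruments.

**Stress-relaxation records** are the forward model plus multiplicative
Gaussian noise. **Linked datasets** draw per-construct lifetimes (baseline
+ day drift + treatment offset + noise) and generate biochemistry and
moduli through linear links with Gaussian noise; defaults give lifetimes of
3.3–5.3 ns, collagen of 1–4% and GAG of 4–8% wet weight, and moduli in the
hundreds of kPa — the ranges typical of maturing self-assembled cartilage —
with link noise placing the population R² near 0.7, a strong but imperfect
optical–destructive correlation.

## Problem sizes and runtime choices

The shipped tests run the full chain at sizes a laptop handles comfortably:
32–48 px FLIm rasters over 60–100 ns windows, 1.6 mm³-scale RF phantoms with
9 frames of 80 lines, twenty seeds per void level, a 3×3×3 biphasic
parameter grid, and 200 seeded linked datasets. These sizes were chosen so
that statistical assertions (recovery within ±2 void points in ≥90% of
seeds; slope coverage ≥93%) have enough replication to be meaningful while
the whole suite stays in the tens of minutes.

## Known limitations

* Voids smaller than about the 200 µm frame spacing are undersampled in
  elevation; their volume is reconstructed from one or two cross-sections
  and is systematically low by tens of percent of the (small) void volume.
* Shape-based interpolation approximates curved caps with cones.
* The homogeneity index inherits every segmentation setting; HS is only as
  good as the void segmentation, and HF2/HF3 treat the lifetime
  distribution pixel-wise, ignoring spatial arrangement (a checkerboard and
  a half-split sample score identically).
* The biphasic model assumes infinitesimal strain, intrinsic
  incompressibility of both phases, strain-independent permeability, and
  frictionless impermeable platens; fitted parameters are
  model-conditional.
* The lifetime centroid is a model-free statistic, not a multi-component
  decay analysis; it matches the decay constant only for effectively
  mono-exponential pixels.
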