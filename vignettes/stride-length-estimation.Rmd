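---
title: "Deriving and evaluating acceleration-based stride-length models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating acceleration-based stride-length models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridelen)
```

## The problem

Pedestrian dead reckoning accumulates a walker's position from per-step
length and heading estimates, so the step (or stride) length model is the
accuracy bottleneck. Classical single-constant models map one inertial
quantity to a length: Weinberg's inverted-pendulum form
$K\,(a_{max}-a_{min})^{1/4}$ on vertical acceleration, Kim's
$K\,\bar a^{1/3}$ on walking-direction acceleration, Zijlstra–Hof's
$2K\sqrt{2LV-V^2}$ on the vertical pelvis excursion $V$ and leg length
$L$, and Tian's $K\,h\sqrt{F}$ on step frequency $F$ and body height $h$.
All of the acceleration-based forms need a known sensor orientation,
which a phone in a pocket does not offer.

This package implements, end to end, the derivation and evaluation of an
alternative: a power law on the within-stride **range of the acceleration
magnitude**,

$$ \hat d = \beta \, a_{range}^{\,0.1}, \qquad
   a_{range} = \max_t |\vec a(t)| - \min_t |\vec a(t)| , $$

whose input is invariant under any fixed rotation of the sensor axes. The
exponent 0.1 is treated as a fixed model constant; $\beta$ is the single
tunable constant, fitted by least squares exactly like the comparators'
constants. An optional grid refit of the exponent exists
(`derive_sl_model(refit_exponent = TRUE)`) but is off by default: the
model form, not the exponent, is what the derivation machinery selects.

## The derivation machinery

The model is not postulated but *selected* from marker kinematics:

1. **Conditioning** (`preprocess_trajectory`, `preprocess_accel`): marker
   occlusions are filled by cubic splines (interior gaps only; boundary
   gaps refuse to extrapolate), positions are low-pass filtered with a
   zero-phase fourth-order Butterworth at 5 Hz, phone accelerations are
   linearly resampled to 100 Hz and wavelet-denoised.
2. **Kinematics** (`derive_kinematics`): velocity and acceleration by
   central finite differences (one-sided at the ends), each derivative
   smoothed with a 10-sample centered moving average; per-sample speed and
   acceleration magnitude alongside.
3. **Stride features** (`build_feature_matrix`): per stride, 28 parameters
   — duration; traveled path in x, y, z; mean, median and range of the
   velocity and acceleration components and magnitudes.
4. **Screening and ranking** (`rank_candidates`): parameters whose
   variance inflation factor exceeds 10 are excluded; each survivor is
   ranked by the residuals of a single-regressor least-squares fit of the
   centered stride lengths on the centered parameter.
5. **Fit** (`derive_sl_model` / `sl_model`): the top-ranked parameter
   enters the power law; $\hat\beta = \sum_i g_i d_i / \sum_i g_i^2$ with
   $g_i = a_{range,i}^{0.1}$, the single-regressor least-squares solution.

Principal components (`sl_pca`, `pcr_fit`) are computed from the SVD of
the column-centered matrix, with eigenvalues in descending order and each
eigenvector's largest-magnitude loading made positive so that output is
identical across linear-algebra backends. Retaining all components
reproduces ordinary least squares exactly — the consistency property the
test suite checks against an explicit covariance eigendecomposition.

```{r derive}
fm <- simulate_feature_matrix(n = 300, noise_sd = 0.03, seed = 42)
derive_sl_model(fm)
```

### Design points the sources leave open

* **Ranking criterion.** The absolute *sum* of residuals of a centered
  single-regressor fit is identically zero by construction, so it cannot
  discriminate candidates. The default criterion is therefore the sum of
  *absolute* residuals of that fit; the absolute residual sum of the
  corresponding uncentered fit is implemented as an alternative
  (`criterion = "abs_sum_resid_uncentered"`), and both quantities are
  reported for every survivor. Ties break by column order.
* **VIF scale.** VIFs are computed on columns standardized to zero mean
  and unit sum of squares. This is what makes "uncorrelated columns have
  VIF 1" hold exactly; on raw scales the diagonal of the inverse
  cross-product matrix is unit-dependent. Exact collinearity yields
  `Inf`, not an error. The threshold 10 is the classical rule of thumb
  and is configurable.
* **Traveled path.** Read as total variation (sum of absolute
  sample-to-sample increments), not net displacement: on a treadmill the
  net walking-direction displacement is approximately zero for every
  stride, which would make the column degenerate. Net displacement is
  available via `path = "net"`.
* **Even smoothing windows.** A 10-sample centered window cannot be
  symmetric; the center is offset toward the earlier sample (samples
  $i-5 \dots i+4$), with shrinking windows at the edges.
* **Indices.** All indices are 1-based (R convention); stride windows are
  half-open `[start, end)` so consecutive strides tile without overlap.

## Signal conditioning choices

* **Zero-phase filtering.** The Butterworth filter is applied forward and
  backward so gait-event timing is not lagged; the effective gain at the
  cutoff is $|H|^2 = 1/2$. `signal::filtfilt` alone has large edge
  transients, so the filter runs on a mean-removed series padded at both
  ends with an odd (point-symmetric) reflection sized to roughly three
  cutoff periods; this gives exact DC passthrough and clean steady-state
  behavior, both asserted in the tests.
* **Wavelet denoising.** No wavelet package ships with the environment's
  R stack, so the package implements a periodized orthogonal DWT with the
  standard sym4 (least-asymmetric, 4 vanishing moments) filter bank, 4
  decomposition levels (capped so at least 8 approximation coefficients
  remain), and soft thresholding at the universal threshold
  $\hat\sigma\sqrt{2\log n}$ with $\hat\sigma$ the MAD of the finest
  detail coefficients over 0.6745 — the Donoho–Johnstone recipe.
  Signals are processed about their mean, so constants pass through
  bit-exactly; perfect reconstruction is property-tested.
* **Double integration** (`vertical_displacement`). The Zijlstra–Hof
  input $V$ comes from integrating vertical acceleration twice with drift
  control. Gait is cyclic — net vertical velocity and displacement per
  stride are zero — but over a one-stride window both a least-squares
  line and an endpoint-anchored line are badly biased by the periodic
  velocity itself (the time-weighted integral of a sinusoid over whole
  periods is not zero, and single endpoint samples sit at
  sample-quantization phase offsets). The drift slope is therefore
  estimated from the difference of the first- and second-half velocity
  means — exact for a genuine linear ramp, nearly blind to whole-period
  oscillations — and the intercept from zero net displacement.

## Event detection

Heel strikes are local maxima of the heel's walking-direction
displacement. Peak picking uses topographic prominence (threshold: 0.3 of
the series' inter-decile range) and a minimum separation of 0.4 expected
stride periods; plateau maxima report their first sample. For the heel
trace the expected period comes from the dominant spectral peak in the
0.3–1.5 Hz stride band. Reference stride lengths are the displacement at
the terminating strike minus the minimum between consecutive strikes (the
anchoring strike is configurable).

Acceleration-magnitude stride segmentation detects one peak per *step*
(impact transients) and keeps alternating peaks, starting from the larger
of the first two, so kept peaks bound same-limb strides. Here the step
period is estimated from the smoothed sample autocorrelation rather than
the spectrum: the magnitude signal's spectrum is dominated by
low-frequency amplitude modulation, and an off-grid period splits its
autocorrelation mass across two lags, which without smoothing loses
against its own exactly-representable multiples. All detector parameters
are scale-free and configurable.

Recordings are synchronized on their dominant spike (the protocol's jump
landing), refined by a windowed cross-correlation argmax. Phone-to-lab
alignment is the Kabsch least-squares proper rotation over three
non-collinear markers; `apply_rotation` then maps phone-frame
accelerations into the lab frame for the orientation-dependent models,
while the magnitude-range input needs no alignment at all — the contrast
the model family exists to exploit.

## What the simulator emulates — and what it does not

`simulate_walk` generates internally consistent treadmill data: the
configuration's defaults are the study conditions used throughout the
tests.

* Speeds 3.3 / 4.6 / 5.9 km/h (slow, normal, fast), 15-minute tracks at
  100 Hz, subject height 1.77 m and leg length 1.05 m — the protocol's
  means. Mean stride length follows speed as $0.8 + 0.12\,v$ (m, v in
  km/h), giving 1.2–1.5 m over the tested range.
* Stride-to-stride variability: length SD 0.02 m and period SD 1% of the
  period (truncated at ±3 SD), matching the 1–2% coefficients of
  variation of healthy treadmill walking. Acceleration noise SD 0.3
  m/s² per axis; marker noise defaults to zero (the optical reference is
  accurate to ~0.1 mm, negligible at these scales).
* Kinematic skeleton: per stride of length $d$, the pelvis oscillates
  vertically twice (once per step) with excursion
  $V = L(1-\cos\theta)$, $d = 2L\sin\theta$ — the inverted-pendulum
  construction, which also makes the Zijlstra–Hof model exact with
  $K = 1$. The heel trace returns to a common baseline at every strike
  with a within-stride dip equal to the drawn stride length, so the
  heel-strike + local-minimum rule recovers truth exactly; short lead-in
  and lead-out ramps from the standing rest position make the first and
  last strikes genuine local maxima.
* Accelerations are analytic second derivatives of the closed-form
  displacements (pelvis), with a Gaussian displacement dip (SD 12 ms,
  snapped to the sampling grid) at every step whose second derivative is
  the heel-strike impact transient — this is what gives the magnitude
  signal its one-peak-per-step structure. Arm, hand and thigh channels
  are phase-shifted, amplitude-scaled copies of the gait fundamental plus
  a stride-frequency harmonic.

The geometry is deliberately idealized: the pendulum construction
exaggerates the vertical excursion relative to real pelvic motion (~0.2 m
versus ~0.03–0.05 m in vivo), there is no left/right asymmetry, no
turning, no soft-tissue artifact, and the distal channels make no
biomechanical fidelity claim. Passing tests therefore demonstrate that
the pipeline's operations are correct and internally consistent under
realistic signal structure and noise — not that the specific error
magnitudes transfer to human data.

## Worked example

```{r pipeline}
walk <- simulate_walk(gait_config(speed_kmh = 4.6, duration_s = 120,
                                  positions = "pelvis", seed = 7))
ds <- stride_dataset(walk)            # heel reference + phone inputs
split <- tuning_split(ds, tuning_s = 40)
fit <- sl_model(ds[split$tuning, ], model = "proposed")
summary(fit)
err <- stride_errors(predict(fit, ds[split$evaluation, ]),
                     ds$length_m[split$evaluation])
round(100 * err$mae, 2)               # held-out MAE in cm
```

Personalized versus universal tuning follows the 5-minute/10-minute
protocol split (`tuning_split`, `pool_tuning_strides`): one constant per
track, or one constant pooled over all tracks' tuning windows. Tracks
shorter than the tuning boundary fall back to a proportional 1/3 : 2/3
split with a warning.

## Problem sizes used by the checks

The package's own verification runs at sizes chosen to exercise every
code path at full protocol scale where it matters: three 15-minute walks
(one per speed) for the end-to-end pipeline, 50 seeded replicates for the
statistical recovery checks (300 strides each), 50 random matrices up to
100 × 28 for the linear-algebra oracle comparisons, and 30–120 second
walks for structural checks. On one CPU the full suite runs in well under
a minute.

## Known limitations

* The 0.1 exponent is taken as given; its provenance is not modeled, and
  the optional grid refit is a convenience, not part of the derivation.
* On the simulator's pelvis-dominated treadmill motion the vertical-axis
  and magnitude acceleration ranges are nearly collinear, so a
  marker-kinematics-only derivation can exclude both under the VIF
  screen; the controlled feature-matrix generator
  (`simulate_feature_matrix`) is the selection test bed.
* Per-axis wavelet denoising does not commute with rotations; the
  orientation-invariance of the magnitude-range input is exact for the
  raw magnitude computation and approximate after denoising.
* Stride windows are sample-quantized; double-integration estimates
  carry an irreducible phase-offset error of a few percent at 100 Hz.
* No left/right disambiguation from a single sensor, no turning
  detection, no streaming (IIR state is not carried between files).
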