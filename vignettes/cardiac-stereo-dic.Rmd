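---
title: "Measuring cardiac surface biomechanics with stereo digital image correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cardiac surface biomechanics with stereo digital image correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioDIC)
```

## The measurement problem

During open-heart surgery the right ventricle (RV) is optically visible but
hard to reach with ultrasound, so its intraoperative mechanics are poorly
monitored. If the surgical team draws a random dot pattern on the exposed
epicardium with a sterile marker, two calibrated cameras can film the
beating surface and subset-based digital image correlation (DIC) can track
it, yielding full-field displacement, strain, and the clinically familiar
descriptors normally read off tissue Doppler: tissue velocity with its
systolic and diastolic peaks (TVs, TVe, TVa), strain rate with SRs, SRe,
SRa, peak-to-peak strain Ss, and fractional shortening (FS) from a virtual
extensometer.

No intraoperative image data is publicly deposited, so the package is
organised around a synthetic beating-heart simulator with exact analytic
ground truth. Every downstream stage — 2D subset tracking, stereo
calibration/triangulation, and the cardiac metrics — is validated against
that ground truth, and published patient-scale magnitudes serve only as
plausibility ranges for the simulator defaults.

## The synthetic heart surface

The simulator deforms a planar speckled patch by a superposition that
mirrors what the epicardium actually does:

* a **beat waveform** `w(t)` in [0, 1], piecewise-cosine with four
  clinically named phases — systolic contraction, early-diastolic (E)
  recovery of a fraction `r_e` of the contraction, a diastasis plateau,
  and an atrial (A) kick completing relaxation;
* a **homogeneous contraction** about a centre: the in-plane scale is
  `c(t) = 1 - a w(t)`, with per-axis anisotropy multipliers;
* a **rigid translation** `T w(t)` (three components; the z component is
  the out-of-plane motion a single camera cannot resolve);
* a **respiration envelope** `1 + m sin(2 pi f_resp t)` multiplying the
  whole displacement — the ventilator slowly modulates every amplitude.

Because the in-plane map is affine, the imposed Green–Lagrange strain is
spatially constant and every derived quantity (extensometer length, FS,
strain rate) has a closed form. Frames are rendered by inverse-mapping
each output pixel through the motion and the camera homography and
sampling the clean reference pattern; per-frame sensor noise is added
last, so the geometry is exact at every pixel.

Parameter defaults and the reasoning behind them:

| parameter | default | why |
|---|---|---|
| heart rate | 60 bpm | typical intraoperative rate |
| frame rate | 17 Hz | middle of the 15–20 Hz acquisition band |
| phases s/E/diastasis/A | 0.30/0.20/0.25/0.25 of the period | at 15–20 Hz an atrial ramp must span at least ~4 samples to be detectable at all; shorter A phases make TVa/SRa undefined at these rates |
| early recovery `r_e` | 0.8 | leaves a distinct atrial contribution |
| contraction `a` | 0.2 | gives a 20% extensometer FS peak, the magnitude scale reported for RV surface shortening |
| translation (full frame) | (14, −8, 10) mm | with the contraction term, ROI-mean peak vector length ≈ 25 mm and peak out-of-plane excursion ≈ 10 mm, the reported magnitude scales |
| respiration | 12 /min, depth 0.08 | visible amplitude modulation across 5–11 beats without destroying beat periodicity |
| speckle | 2 dots/mm², radius 0.30 ± 0.06 mm, dark-on-light | ≈50–60% ink coverage, standard DIC pattern practice; dark dots on pale fat is the marker-on-epicardium contrast polarity |
| pattern margin | 6 mm | the tissue continues beyond the analysed patch; subsets near the patch edge must stay textured under motion |

Desk-scale runs (tests, examples) use 256–512 px frames at 0.1 mm/px with
proportionally smaller in-plane translations (a few mm), because a 25 mm
excursion does not fit a 51 mm field of view; the full 2055×1788 px frame
geometry is reserved for the camera models and calibration checks.

What the simulator does **not** emulate: surface curvature (the patch is
planar; real RV surfaces curve and tilt), specular wet-tissue highlights,
heterogeneous regional contraction, epicardial-fat mechanics, and ECG
timing. Passing the synthetic benchmarks therefore demonstrates that the
tracking and metrics chain is correct and noise-robust under realistic
magnitudes, not that patient images of arbitrary quality will track.

## The correlation engine

Tracking follows the standard modern subset-DIC recipe:

* **Criterion**: zero-normalised SSD (reported as ZNCC), exactly invariant
  to affine lighting changes — surgical lights drift.
* **Shape function**: first-order affine subset warp. At subset sizes of
  31–79 px and steps of 10–12 px the quadratic terms of the cardiac
  motions used here are negligible.
* **Optimiser**: inverse-compositional Gauss–Newton; the Hessian is built
  once per reference subset. Convergence at an update norm of 1e-4 px,
  at most 50 iterations. When no seed is available, or the converged
  match has ZNCC below 0.8 (the signature of a false lock on a
  neighbouring speckle), an integer ZNCC search (±10 px) re-seeds one
  retry and the better converged match wins.
* **Interpolation**: prefiltered cubic B-splines (recursive prefilter,
  mirror boundaries) for subset sampling, gradients, and rendering.
  Compared with cubic-convolution kernels this cuts the systematic
  sub-pixel phase bias by an order of magnitude — decisive here because
  the sum-of-differentials mode adds one interpolation bias per frame
  pair, all with similar phase.
* **Accumulation**: `incremental` correlates consecutive frames with the
  subset centres riding on the material points and sums the increments
  (errors accumulate along the chain, which is why per-beat analysis and
  stitching exist); `to_reference` correlates every frame against frame
  one seeded by the incremental estimate. Their agreement is itself a
  validation statistic. Per-point cumulative quality is the minimum ZNCC
  along the chain; invalid points carry explicit masks, never sentinel
  values.

Coordinates are 1-based pixel centres, x rightward (columns), y downward
(rows), origin at the top-left pixel; all exports state mm conversions
explicitly.

## Stereo geometry

Calibration uses the direct linear transform on at least six non-coplanar
points of a 3D target, refined by quasi-Newton minimisation of the
reprojection error; the calibration error is the RMS of per-point
distances between reprojected and measured positions, which lands in the
~0.1 px (~0.01 mm at 0.1 mm/px) regime under 0.1 px image noise. Lens
distortion is not modelled — the synthetic cameras are ideal pinholes and
no distortion data exists for the application — but the camera type keeps
the projection matrix as its single point of extension. Cross-camera
correspondence runs once on the reference frames (geometry-seeded integer
search plus affine refinement); temporal tracking stays per-camera, and
per-frame triangulation of the left/right tracks gives 3D displacements in
the calibration-target (world) frame. The out-of-plane component `u_z` only
exists in stereo runs; single-camera runs flag it absent rather than
zero-filling.

## Cardiac metrics

* **ROI traces**: per-frame mean and SD over valid ROI grid points of each
  displacement component and of the per-point vector length `|u|`
  (averaged per point, not the length of the mean vector). A frame with
  fewer than 25% valid ROI points is reported missing.
* **Beat segmentation**: local minima of `V_l` with topographic prominence
  of at least `prominence_frac` (default 0.3) of the global range,
  separated by `min_beat_s` (default 0.4 s). A trace that starts or ends
  at its resting level contributes that boundary; leading/trailing partial
  beats are excluded from per-beat statistics. Manual intervals can be
  supplied through the configuration.
* **Tissue velocity**: Savitzky–Golay smoothing (local quadratic, default
  window 5 — the smallest window that stabilises ±1-frame extremum
  detection at 15–20 Hz) followed by central differences, in cm/s.
  TVs/TVe are the per-beat positive/negative extrema; TVa is the most
  negative local minimum strictly after TVe, required to exceed 2% of the
  velocity scale so smoothing ripple on a flat diastasis is never
  reported as an atrial kick — an absent TVa is flagged, not imputed.
* **Strain field**: windowed least-squares displacement gradients on the
  regular lattice, Green–Lagrange tensor, principal stretches reported as
  engineering principal strains — finite-strain correct at the 100%+
  magnitudes seen with an end-systolic reference and exactly
  rotation-invariant. The reference state defaults to the sequence start;
  `reference = "end_systole"` re-references each beat to its
  most-contracted frame, reproducing the convention under which surface
  strains of +100–150% are reported.
* **Virtual extensometer**: endpoint displacements by inverse-distance
  weighting over the nearest valid grid points (at least three), length in
  3D when available. `FS(t) = (1 - L(t)/L_max) × 100` with `L_max` the
  per-beat maximum (end-diastolic) length, so FS is in [0, 100) and
  reaches 0 in every beat; the conventional echo definition
  `(LVEDD - LVESD)/LVEDD × 100` is provided alongside. Strain uses the
  same per-beat reference; strain rate is the smoothed derivative of
  strain/100 (1/s) with SRs/SRe/SRa detected per beat and
  `Ss = max - min` strain per beat. Directional (longitudinal/horizontal)
  strains use a second, perpendicular extensometer of equal initial
  length through the midpoint, shortened with a warning if it would leave
  the grid.

Sign conventions: image-left motion is negative `V_y`-direction
displacement in image coordinates; velocity is positive when `|u|` grows
(motion towards the apex in the clinical reading).

## Numerical choices and edge cases

* Bit depths 8/16 are supported; intensities are carried as doubles.
* The beat waveform is continuous everywhere; with zero respiration depth
  the ground-truth motion is exactly periodic, which the tests exploit.
* Degenerate inputs fail loudly with named conditions:
  `out-of-view`, `tracking-collapse`, `correspondence-collapse`,
  `degenerate-target`, `insufficient-points`, `ill-conditioned`,
  `segmentation-failure`, `stitching-gap`, `empty-field`,
  `invalid-window`, `invalid-length`, `invalid-dimension`.
* Seeds are explicit on every stochastic input (pattern, noise,
  calibration noise); re-running a configuration reproduces all outputs
  bitwise, which the pipeline test asserts on the CSV files.
* B-spline interpolation reproduces polynomials exactly in the image
  interior; within ~15 px of a border the mirror boundary makes linear
  reproduction approximate (error decaying as `0.27^d`), one reason
  subsets keep a margin from the frame edge.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen to exercise every code path while staying
laptop-friendly: shift/drift benchmarks on 256×256 px patterns with ~200
grid points; one 100-frame 512×512 px stereo run at 17 Hz (five beats,
20% contraction, 10 mm out-of-plane translation) for end-to-end parameter
recovery; and one ~157-frame single-camera run with noise and respiration
modulation across 11 beats for repeatability of the per-beat peak strain.
Monte-Carlo noise studies use 100–200 seeds. The full-resolution
2055×1788 px geometry appears in the calibration/triangulation checks,
where it is cheap.

## Known limitations

* Planar surface patch: no curvature, so stereo validation exercises
  out-of-plane *translation*, not shape reconstruction.
* Pinhole cameras without distortion, matched to the distortion-free
  synthetic data.
* Equivalence with any specific commercial DIC implementation cannot be
  asserted — correlation criteria and seeding strategies of such suites
  are proprietary — only agreement with analytic ground truth.
* The tissue-velocity definition used here is the signed rate of change
  of the vector length; if a future comparison study requires a projected
  apex-directed component instead, it should be added as a separate
  trace rather than redefining this one.
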