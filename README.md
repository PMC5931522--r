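# cardioDIC

Stereo digital image correlation (DIC) for quantifying the motion and
deformation of the beating heart surface — in particular the right
ventricle (RV), which is optically visible during open-heart surgery but
hard to reach with intraoperative ultrasound. Given grayscale image
sequences of a speckle-patterned surface from one or two calibrated
cameras, the package tracks a grid of correlation subsets with subpixel
precision, lifts the 2D fields to 3D by triangulation, and derives the
descriptors used in clinical monitoring:

- displacement components `V_x`, `V_y`, `V_z` and vector length `V_l`,
  ROI-averaged with per-frame dispersion;
- maximum/minimum principal strains from windowed Green–Lagrange strain
  fields (optionally referenced to end-systole);
- tissue velocity `d|u|/dt` with peak systolic (TVs), peak early-diastolic
  (TVe) and peak late-diastolic (TVa) values;
- fractional shortening from a virtual extensometer,
  `FS(t) = (1 − L(t)/L_max) × 100%` with `L_max` the per-beat maximum
  (end-diastolic) length, alongside the conventional
  `FS = (LVEDD − LVESD)/LVEDD × 100%`;
- extensometer strain and strain rate with SRs/SRe/SRa and the per-beat
  peak-to-peak strain Ss;
- beat segmentation from `V_l` minima, with per-beat analysis and
  stitching of per-beat fields ("sum of differentials" accumulation makes
  errors grow along a sequence; per-beat tracking bounds them).

The correlation engine is a first-order inverse-compositional
Gauss–Newton solver on the zero-normalised SSD criterion with prefiltered
cubic B-spline interpolation, integer ZNCC search seeding, and false-lock
recovery. Stereo calibration is DLT + refinement on a 3D target, with the
calibration error reported as the RMS distance between reprojected and
known point positions.

Because no intraoperative imaging data is publicly deposited, the package
includes a first-class synthetic beating-heart simulator
(`generate_stereo_sequences()`): a speckled surface driven by a
piecewise-cosine beat waveform (systole, early-diastolic recovery,
diastasis, atrial kick), homogeneous contraction, rigid 3D translation and
respiration amplitude modulation — with exact analytic ground truth for
displacement, strain and extensometer length. All validation is against
this ground truth; published patient-scale magnitudes (vector length
~25 mm, tissue velocity ±10 cm/s, FS ~20%, calibration ~0.1 px) serve as
plausibility ranges for the defaults.

## Worked example

Simulate a five-beat stereo sequence (100 frames, 512×512 px, 17 Hz,
0.1 mm/px, 20% contraction, 10 mm out-of-plane translation), track both
cameras, triangulate, and extract the cardiac descriptors:

```r
library(cardioDIC)

pattern <- speckle_pattern_params(noise_sigma = 1, seed = 42)
motion  <- motion_model_params(contraction_amplitude = 0.2,
                               translation_amplitude = c(3, -2, 10),
                               respiration_mod_depth = 0, seed = 42)
rig <- stereo_rig(c(512, 512), mm_per_px = 0.1)
sim <- generate_stereo_sequences(pattern, motion, rig, n_frames = 100,
                                 frame_rate = 17, patch_size_mm = c(32, 32))

grid  <- subset_grid(c(136, 136, 241, 241), c(512, 512),
                     subset_size = 31, step = 12)
left  <- accumulate_sequence(sim$cam1, grid, "incremental", mm_per_px = 0.1)
right <- accumulate_sequence(sim$cam2, grid, "incremental", mm_per_px = 0.1)
corr  <- stereo_correspond(sim$cam1$frames[[1]], sim$cam2$frames[[1]],
                           grid, rig[[1]], rig[[2]])
field <- lift_fields_to_3d(left, right, corr, rig[[1]], rig[[2]])

traces <- roi_traces(field, roi_def(140, 140, 233, 233))
beats  <- segment_beats(traces$V_l)
ext    <- extensometer_def(c(256, 160), c(256, 352))
L      <- extensometer_length(field, ext)
fs     <- fractional_shortening(L, beats)
tv     <- tissue_velocity(traces$V_l)
detect_tv_points(tv, beats)
```

This prints:

```
Beat segmentation: 5 complete beats (boundaries at frames 1, 18, 35, 52, 69, 86)
FS peak: 20.0 % | V_l peak: 10.79 mm | u_z peak: 10.00 mm | TV range: -5.3 / +5.1 cm/s
  beat      TVs TVs_frame       TVe TVe_frame       TVa TVa_frame
     1 5.084269         4 -5.262258         8 -1.241675        16
     2 5.084438        21 -5.262268        25 -1.241000        33
     3 5.084398        38 -5.262221        42 -1.240237        50
```

All five imposed beats are found at their exact boundaries, the
extensometer fractional shortening recovers the imposed 20% contraction,
the triangulated out-of-plane peak recovers the imposed 10 mm translation,
and the systolic/E/A tissue-velocity peaks repeat beat for beat. The
vector-length and tissue-velocity magnitudes scale with the (desk-scale)
translation amplitudes; full-frame defaults produce the ~25 mm / ±10 cm/s
clinical magnitude ranges.

The same chain is available from a shell via the thin CLI at
`inst/cli/cardiodic` (`simulate`, `calibrate`, `track`, `analyze`, `run`,
`report`), driven by a YAML configuration, and as one call through
`run_pipeline()`, which also writes CSV traces, figures and a
reproducibility manifest.

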