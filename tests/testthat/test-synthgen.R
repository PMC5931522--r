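test_that("speckle rendering is seeded, validated, and density-faithful", {
  pp <- speckle_pattern_params(seed = 7)
  a <- render_speckle_pattern(pp, 120, 100, 0.1)
  b <- render_speckle_pattern(pp, 120, 100, 0.1)
  expect_identical(a, b)                       # bitwise determinism

  # empty pattern: uniform background
  pp0 <- speckle_pattern_params(dot_density = 0, noise_sigma = 0)
  img <- render_speckle_pattern(pp0, 50, 40, 0.1)
  expect_equal(max(abs(img - pp0$background_intensity)), 0, tolerance = 1e-9)

  expect_error(render_speckle_pattern(pp, -5, 100, 0.1), "invalid-parameter")
  expect_error(speckle_pattern_params(dot_density = -1), "invalid-parameter")
  expect_error(speckle_pattern_params(dot_intensity = 500), "invalid-parameter")

  # Poisson dot-count oracle: density 2 /mm^2 over a 10 x 10 mm field
  for (s in 1:5) {
    pp2 <- speckle_pattern_params(dot_density = 2, seed = s)
    n <- attr(render_speckle_pattern(pp2, 100, 100, 0.1), "n_dots")
    expect_gt(n, 200 * 0.8)
    expect_lt(n, 200 * 1.2)
  }
})

test_that("cardiac scale realises the designed beat waveform", {
  mot <- motion_model_params(heart_rate = 75, contraction_amplitude = 0.2,
                             early_recovery_ratio = 0.8)
  Tb <- 60 / mot$heart_rate
  expect_equal(cardiac_scale(mot, 0), 1.0)
  expect_equal(cardiac_scale(mot, mot$systole_fraction * Tb), 0.8)
  # plateau value from the piecewise formula: 1 - a + r_e * a
  expect_equal(cardiac_scale(mot,
    (mot$systole_fraction + mot$early_diastole_fraction) * Tb), 0.96)
  tt <- seq(0, 3 * Tb, length.out = 2000)
  cc <- cardiac_scale(mot, tt)
  expect_true(all(cc >= 1 - mot$contraction_amplitude - 1e-12 & cc <= 1 + 1e-12))
  expect_lt(max(abs(diff(cc))), 0.01)          # continuity
  expect_error(beat_waveform(mot, -1), "invalid-parameter")
})

test_that("ground-truth displacement follows the stated superposition", {
  mot <- motion_model_params(contraction_amplitude = 0.2,
                             translation_amplitude = c(0, 0, 0),
                             respiration_mod_depth = 0)
  X <- rbind(c(10, 0), c(0, 5), c(-3, -7))
  expect_equal(true_displacement(mot, X, 0), matrix(0, 3, 3),
               ignore_attr = TRUE)
  # contraction centre is a fixed point of pure contraction
  for (t in c(0.1, 0.33, 0.7))
    expect_equal(as.numeric(true_displacement(mot, c(0, 0), t)), c(0, 0, 0))
  # (c - 1) * (X - Xc) at end-systole, c = 0.8
  Tb <- 60 / mot$heart_rate
  u <- true_displacement(mot, c(10, 0), mot$systole_fraction * Tb)
  expect_equal(as.numeric(u), c(-2, 0, 0), tolerance = 1e-12)
})

test_that("motion is periodic without respiration and modulated with it", {
  mot <- motion_model_params(translation_amplitude = c(4, -2, 6),
                             respiration_mod_depth = 0)
  X <- rbind(c(8, -6), c(-4, 9))
  Tb <- 60 / mot$heart_rate
  for (t in c(0.12, 0.4, 0.83))
    expect_equal(true_displacement(mot, X, t),
                 true_displacement(mot, X, t + Tb), tolerance = 1e-12)
  mot2 <- motion_model_params(translation_amplitude = c(4, -2, 6),
                              respiration_mod_depth = 0.1,
                              respiration_rate = 13)
  expect_false(isTRUE(all.equal(true_displacement(mot2, X, 0.4),
                                true_displacement(mot2, X, 0.4 + Tb))))
  env <- respiration_envelope(mot2, seq(0, 60, by = 0.01))
  expect_equal(range(env), c(0.9, 1.1), tolerance = 1e-4)
})

test_that("imposed strain is homogeneous and matches the affine map", {
  mot <- motion_model_params(contraction_amplitude = 0.15,
                             anisotropy = c(1, 0.6),
                             translation_amplitude = c(3, 1, 2))
  t <- 0.21
  st <- true_strain(mot, t)
  # numerical gradient of the displacement field at scattered points
  for (X in list(c(0, 0), c(11, -7), c(-9, 13))) {
    h <- 1e-4
    dux <- (true_displacement(mot, X + c(h, 0), t) -
              true_displacement(mot, X - c(h, 0), t)) / (2 * h)
    duy <- (true_displacement(mot, X + c(0, h), t) -
              true_displacement(mot, X - c(0, h), t)) / (2 * h)
    Fm <- diag(2) + rbind(dux[1:2], duy[1:2])
    E <- (t(Fm) %*% Fm - diag(2)) / 2
    expect_equal(E[1, 1], st$Exx, tolerance = 1e-7)
    expect_equal(E[2, 2], st$Eyy, tolerance = 1e-7)
    expect_equal(E[1, 2], st$Exy, tolerance = 1e-7)
  }
})

test_that("static scenes are frame-identical and gross motion leaves the view", {
  pp <- speckle_pattern_params(noise_sigma = 0, seed = 3)
  still <- motion_model_params(contraction_amplitude = 0,
                               translation_amplitude = c(0, 0, 0),
                               respiration_mod_depth = 0)
  rig <- stereo_rig(c(128, 128), 0.1, 1000, 12)
  sim <- generate_stereo_sequences(pp, still, rig, 4, 17,
                                   patch_size_mm = c(8, 8), margin_mm = 2)
  for (k in 2:4) {
    expect_identical(sim$cam1$frames[[k]], sim$cam1$frames[[1]])
    expect_identical(sim$cam2$frames[[k]], sim$cam2$frames[[1]])
  }
  expect_true(all(sim$ground_truth$u == 0))

  runaway <- motion_model_params(contraction_amplitude = 0,
                                 translation_amplitude = c(500, 0, 0),
                                 respiration_mod_depth = 0)
  expect_error(generate_stereo_sequences(pp, runaway, rig, 6, 17,
                                         patch_size_mm = c(8, 8),
                                         margin_mm = 2),
               "out-of-view.*frame")
})

test_that("stereo generation is deterministic and internally consistent", {
  run <- function() desk_simulation(n_frames = 4, image_px = 128,
                                    patch_mm = 8, translation = c(1, -1, 2))
  s1 <- run(); s2 <- run()
  expect_identical(s1$cam1$frames, s2$cam1$frames)
  expect_identical(s1$cam2$frames, s2$cam2$frames)
  expect_identical(s1$ground_truth$u, s2$ground_truth$u)
  expect_length(s1$cam1$frames, 4)

  gt <- s1$ground_truth
  expect_true(all(gt$u[1, , ] == 0))   # reference state
  expect_true(all(gt$L_mm > 0))
})

test_that("extensometer ground truth equals the scale factor for axis-aligned contraction", {
  sim <- desk_simulation(n_frames = 10, image_px = 128, patch_mm = 8,
                         translation = c(2, -1, 0), contraction = 0.18,
                         heart_rate = 120)
  gt <- sim$ground_truth
  # vertical extensometer, isotropic contraction, pure translation:
  # L(t)/L(0) must equal the effective contraction scale exactly
  sy <- 1 + gt$M * (gt$c - 1)
  expect_equal(gt$L_mm / gt$L_mm[1], sy, tolerance = 1e-12)
})

test_that("calibration views satisfy the projections and reject degenerate targets", {
  rig <- stereo_rig(c(512, 512), 0.1, 1000, 15)
  target <- calibration_target(10, 40, 20)
  tab <- render_calibration_views(target, rig, pixel_noise_sigma = 0)
  for (i in seq_len(nrow(tab))) {
    p1 <- reproject(rig[[1]], as.numeric(tab[i, c("X_mm", "Y_mm", "Z_mm")]))
    expect_equal(as.numeric(tab[i, c("cam1_x_px", "cam1_y_px")]), p1,
                 tolerance = 1e-10)
  }
  coplanar <- cbind(calibration_target(8, 40, 0)[1:8, 1:2], Z = 0)
  expect_error(render_calibration_views(coplanar, rig), "degenerate-target")
  expect_error(render_calibration_views(target[1:5, ], rig),
               "insufficient-points")

  # Monte-Carlo noise model: injected pixel noise has the requested std
  devs <- unlist(lapply(1:200, function(s) {
    tb <- render_calibration_views(target, rig, pixel_noise_sigma = 0.1,
                                   seed = s)
    c(tb$cam1_x_px - tab$cam1_x_px, tb$cam1_y_px - tab$cam1_y_px,
      tb$cam2_x_px - tab$cam2_x_px, tb$cam2_y_px - tab$cam2_y_px)
  }))
  expect_equal(sd(devs), 0.1, tolerance = 0.02)
})
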