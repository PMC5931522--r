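test_that("ROI traces average per-point components and vector length", {
  zero <- make_synth_field(function(x, y, k) cbind(0 * x, 0 * x, 0 * x),
                           n_frames = 3)
  roi <- roi_def(40, 40, 121, 121)
  tr <- roi_traces(zero, roi)
  expect_equal(max(abs(tr$V_l$values)), 0)
  expect_equal(max(abs(tr$V_l$sd)), 0)

  # uniform u = (3, 4, 0) mm: the 3-4-5 triangle
  s <- 0.1
  uni <- make_synth_field(function(x, y, k)
    cbind(rep(3 / s, length(x)), rep(4 / s, length(x)), 0) * (k - 1),
    n_frames = 2)
  tr <- roi_traces(uni, roi)
  expect_equal(tr$V_x$values[2], 3, tolerance = 1e-12)
  expect_equal(tr$V_y$values[2], 4, tolerance = 1e-12)
  expect_equal(tr$V_l$values[2], 5, tolerance = 1e-12)
  expect_equal(tr$V_l$sd[2], 0, tolerance = 1e-12)

  expect_error(roi_traces(zero, roi_def(0, 0, 5, 5)), "invalid-parameter")
})

test_that("beat segmentation finds sinusoid minima and rejects flat traces", {
  t <- seq(0, 10, by = 0.05)
  vl <- dic_trace(sin(2 * pi * t), t, label = "V_l", units = "mm")
  beats <- segment_beats(vl, min_beat_s = 0.4, prominence_frac = 0.3)
  expect_equal(nrow(beats$intervals), 9)   # 9 complete interior beats
  # minima of sin at t = 0.75 + k
  expect_equal(vl$time[beats$boundaries], 0.75 + 0:9, tolerance = 1e-9)

  flat <- dic_trace(rep(2, 50), seq(0, 2.45, by = 0.05))
  expect_error(segment_beats(flat), "segmentation-failure")
})

test_that("beat stitching offsets by accumulated end-displacement", {
  # one beat: identity
  f <- make_synth_field(function(x, y, k) cbind(0 * x + k - 1, 0 * x),
                        n_frames = 5)
  expect_identical(stitch_beats(list(f)), f)

  # two identical beats, each ending at zero displacement: plain
  # concatenation with zero offset
  wobble <- function(x, y, k) cbind(0 * x + sin(pi * (k - 1) / 4), 0 * x)
  b1 <- make_synth_field(wobble, n_frames = 5)
  b2 <- make_synth_field(wobble, n_frames = 5)
  b2$time <- b2$time + b1$time[5]
  st <- stitch_beats(list(b1, b2))
  expect_equal(nrow(st$u), 9)
  expect_equal(st$u[6:9, ], b1$u[2:5, ], tolerance = 1e-12)

  # a beat ending displaced offsets its successor
  drift <- function(x, y, k) cbind(0 * x + (k - 1), 0 * x)
  d1 <- make_synth_field(drift, n_frames = 4)
  d2 <- make_synth_field(drift, n_frames = 4)
  d2$time <- d2$time + d1$time[4]
  st <- stitch_beats(list(d1, d2))
  expect_equal(st$u[7, 1], 3 + 3, tolerance = 1e-12)

  d3 <- make_synth_field(drift, n_frames = 4)  # non-contiguous times
  expect_error(stitch_beats(list(d1, d3)), "stitching-gap")
})

test_that("tissue velocity is the scaled derivative of the length trace", {
  t <- seq(0, 2, by = 0.05)
  cst <- dic_trace(rep(7, length(t)), t)
  tv <- tissue_velocity(cst)
  expect_equal(max(abs(tv$values)), 0, tolerance = 1e-10)

  # V_l rising 1 mm/frame at 20 Hz = 20 mm/s = 2 cm/s
  ramp <- dic_trace(seq_along(t) * 1.0, t)
  tv <- tissue_velocity(ramp)
  expect_equal(tv$values[10], 2.0, tolerance = 1e-9)
  expect_equal(tv$units, "cm/s")
  expect_error(tissue_velocity(dic_trace(1:3, (0:2) / 20), 5),
               "invalid-window")
})

test_that("TV characteristic points follow their clinical definitions", {
  # analytic beat waveform with distinct E and A phases
  mot <- motion_model_params(heart_rate = 60)
  t <- seq(0, 2, by = 1 / 20)    # exactly two full beats
  vl <- dic_trace(20 * beat_waveform(mot, t), t, label = "V_l", units = "mm")
  beats <- segment_beats(vl)
  tv <- tissue_velocity(vl)
  pts <- detect_tv_points(tv, beats)
  expect_true(all(pts$flag == "ok"))
  expect_true(all(pts$TVs > 0))
  expect_true(all(pts$TVe < 0))
  expect_true(all(pts$TVa < 0 & pts$TVa > pts$TVe))
  # ordering within the beat: systolic peak, then E, then A
  expect_true(all(pts$TVs_frame < pts$TVe_frame))
  expect_true(all(pts$TVe_frame < pts$TVa_frame))

  # analytic timing oracle: extrema of the true derivative of the waveform
  tt <- seq(0, 1, by = 1e-4)
  dv <- diff(20 * beat_waveform(mot, tt)) / 1e-4
  t_tvs <- tt[which.max(dv)]; t_tve <- tt[which.min(dv)]
  b1 <- pts[1, ]
  expect_lt(abs(vl$time[b1$TVs_frame] - t_tvs), 1.5 / 20)
  expect_lt(abs(vl$time[b1$TVe_frame] - t_tve), 1.5 / 20)

  # sign flip swaps the roles of TVs and TVe exactly
  neg <- dic_trace(-tv$values, tv$time, units = "cm/s")
  pn <- detect_tv_points(neg, beats)
  expect_equal(pn$TVs, -pts$TVe)
  expect_equal(pn$TVe, -pts$TVs)
  expect_equal(pn$TVs_frame, pts$TVe_frame)

  # full early recovery and no atrial kick: TVa flagged absent
  mot1 <- motion_model_params(early_recovery_ratio = 1)
  vl1 <- dic_trace(20 * beat_waveform(mot1, t), t, label = "V_l", units = "mm")
  p1 <- detect_tv_points(tissue_velocity(vl1),
                         segment_beats(vl1, min_beat_s = 0.6))
  expect_true(all(p1$flag == "TVa-absent"))
  expect_true(all(is.na(p1$TVa)))
})

test_that("principal strains recover closed-form homogeneous deformations", {
  # u_x = 0.10 x, u_y = -0.05 y about the grid centre
  ctr <- c(100, 100)
  f <- make_synth_field(function(x, y, k)
    (k - 1) * cbind(0.10 * (x - ctr[1]), -0.05 * (y - ctr[2])), n_frames = 2)
  ss <- local_strain_field(f, 3)
  expect_equal(ss$per_frame$e_max[2], 10, tolerance = 0.2)
  expect_equal(ss$per_frame$e_min[2], -5, tolerance = 0.2)
  # zero at the reference frame, and e_max >= e_min everywhere
  expect_equal(ss$per_frame$e_max[1], 0, tolerance = 1e-10)
  expect_true(all(ss$point_e_max >= ss$point_e_min - 1e-12))

  # rigid translation: identically zero
  ft <- make_synth_field(function(x, y, k) cbind(0 * x + 7.3, 0 * x - 4.1),
                         n_frames = 2)
  st <- local_strain_field(ft, 3)
  expect_lt(max(abs(c(st$per_frame$e_max[2], st$per_frame$e_min[2]))), 1e-10)

  # rigid rotation by 10 degrees: Green-Lagrange stays below 0.5%
  th <- 10 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  fr <- make_synth_field(function(x, y, k) {
    if (k == 1) return(cbind(0 * x, 0 * x))
    p <- cbind(x - ctr[1], y - ctr[2]) %*% t(R)
    cbind(p[, 1] - (x - ctr[1]), p[, 2] - (y - ctr[2]))
  }, n_frames = 2)
  sr <- local_strain_field(fr, 3)
  expect_lt(max(abs(c(sr$per_frame$e_max[2], sr$per_frame$e_min[2]))), 0.5)
})

test_that("extensometer length respects rigid motion and pure scaling", {
  roi <- c(40, 40, 121, 121)
  ext <- extensometer_def(c(100, 60), c(100, 140))
  zero <- make_synth_field(function(x, y, k) cbind(0 * x, 0 * x), n_frames = 3)
  L <- extensometer_length(zero, ext)
  expect_equal(L$values, rep(8, 3), tolerance = 1e-12)   # 80 px * 0.1 mm

  shift <- make_synth_field(function(x, y, k)
    cbind(0 * x + 5 * (k - 1), 0 * x - 3 * (k - 1)), n_frames = 3)
  L <- extensometer_length(shift, ext)
  expect_equal(L$values, rep(8, 3), tolerance = 1e-10)

  scale08 <- make_synth_field(function(x, y, k) {
    if (k == 1) cbind(0 * x, 0 * x)
    else cbind(-0.2 * (x - 57), -0.2 * (y - 31))   # c = 0.8 about (57, 31)
  }, n_frames = 2)
  L <- extensometer_length(scale08, ext)
  expect_equal(L$values[2] / L$values[1], 0.8, tolerance = 1e-10)

  expect_error(extensometer_length(zero, extensometer_def(c(1, 1), c(2, 2))),
               "outside the tracked grid")
})

test_that("fractional shortening implements its defining arithmetic", {
  t <- (0:39) / 20
  beats <- make_beats(c(1, 21, 41))
  lmax <- 10
  flat <- dic_trace(rep(lmax, 40), t)
  expect_equal(max(abs(fractional_shortening(flat, beats)$values)), 0)

  shape <- rep(c(1, 0.95, 0.8, 0.9, 1), each = 4)
  L <- dic_trace(lmax * c(shape, shape), t)
  fs <- fractional_shortening(L, beats)
  expect_equal(max(fs$values), 20, tolerance = 1e-12)
  expect_true(all(fs$values >= 0 & fs$values < 100))
  # FS attains 0 within every beat
  for (b in 1:2)
    expect_equal(min(abs(fs$values[beats$intervals[b, 1]:
                                     (beats$intervals[b, 2] - 1)])), 0)

  expect_error(fractional_shortening(dic_trace(rep(-1, 40), t), beats),
               "invalid-length")
})

test_that("conventional FS matches the echo definition", {
  expect_equal(fs_conventional(50, 50), 0)
  expect_equal(fs_conventional(50, 0), 100)
  expect_equal(fs_conventional(50, 37.5), 25)   # M-mode normal lower limit
  expect_error(fs_conventional(0, 0), "invalid-dimension")
  expect_error(fs_conventional(50, 60), "invalid-dimension")
})

test_that("strain and strain rate traces carry the clinical characteristic points", {
  t <- (0:39) / 20
  beats <- make_beats(c(1, 21, 41))
  cst <- dic_trace(rep(9, 40), t)
  out <- strain_and_rate(cst, beats)
  expect_equal(max(abs(out$strain$values)), 0)
  expect_equal(max(abs(out$strain_rate$values)), 0, tolerance = 1e-10)
  expect_equal(out$points$Ss, c(0, 0))

  # linear shortening: rate approximately -0.2 1/s
  lin <- dic_trace(10 * (1 - 0.2 * t), t)
  out <- strain_and_rate(lin, make_beats(c(1, 41)))
  mid <- 10:30
  expect_equal(mean(out$strain_rate$values[mid]), -0.2, tolerance = 0.01)

  # beat-waveform length trace: SRs negative, SRe and SRa positive, ordered
  mot <- motion_model_params(heart_rate = 60)
  tt <- seq(0, 2, by = 1 / 20)
  L <- dic_trace(10 * (1 - 0.2 * beat_waveform(mot, tt)), tt,
                 label = "L", units = "mm")
  beats <- segment_beats(dic_trace(10 - L$values, tt))
  out <- strain_and_rate(L, beats)
  expect_true(all(out$points$flag == "ok"))
  expect_true(all(out$points$SRs < 0))
  expect_true(all(out$points$SRe > 0))
  expect_true(all(out$points$SRa > 0 & out$points$SRa < out$points$SRe))
  expect_true(all(out$points$SRe_frame < out$points$SRa_frame))
  expect_equal(out$points$Ss, rep(20, nrow(out$points)), tolerance = 0.5)
})

test_that("directional strains separate the extensometer axes", {
  ext <- extensometer_def(c(100, 70), c(100, 130))
  ctr <- c(100, 100)
  iso <- make_synth_field(function(x, y, k) {
    if (k == 1) cbind(0 * x, 0 * x)
    else cbind(-0.1 * (x - ctr[1]), -0.1 * (y - ctr[2]))   # c = 0.9
  }, n_frames = 2)
  ds <- directional_strains(iso, ext)
  expect_equal(ds$longitudinal$values[2], -10, tolerance = 1e-8)
  expect_equal(ds$horizontal$values[2], -10, tolerance = 1e-8)

  # uniaxial stretch along the extensometer: horizontal unaffected
  uni <- make_synth_field(function(x, y, k) {
    if (k == 1) cbind(0 * x, 0 * x) else cbind(0 * x, 0.05 * (y - ctr[2]))
  }, n_frames = 2)
  ds <- directional_strains(uni, ext)
  expect_equal(ds$longitudinal$values[2], 5, tolerance = 1e-8)
  expect_equal(ds$horizontal$values[2], 0, tolerance = 1e-8)

  # rigid rotation: both strains under 0.5%
  th <- 8 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot <- make_synth_field(function(x, y, k) {
    if (k == 1) return(cbind(0 * x, 0 * x))
    p <- cbind(x - ctr[1], y - ctr[2]) %*% t(R)
    cbind(p[, 1] - (x - ctr[1]), p[, 2] - (y - ctr[2]))
  }, n_frames = 2)
  ds <- directional_strains(rot, ext)
  expect_lt(abs(ds$longitudinal$values[2]), 0.5)
  expect_lt(abs(ds$horizontal$values[2]), 0.5)
})

test_that("end-systole strain referencing yields tension relative to the contracted state", {
  # contraction to c = 0.8 and back over one cycle
  ctr <- c(100, 100)
  shape <- c(0, 0.5, 1, 0.5, 0, 0, 0.5, 1, 0.5, 0)
  f <- make_synth_field(function(x, y, k)
    -0.2 * shape[k] * cbind(x - ctr[1], y - ctr[2]), n_frames = 10)
  vl <- roi_traces(f, roi_def(40, 40, 121, 121))$V_l
  beats <- segment_beats(vl, min_beat_s = 0.1)
  ses <- local_strain_field(f, 3, reference = "end_systole", beats = beats)
  # relative to end-systole (c = 0.8) the dilated state is 1/0.8 - 1 = +25%
  expect_equal(max(ses$per_frame$e_max, na.rm = TRUE), 25, tolerance = 0.5)
  expect_error(local_strain_field(f, 3, reference = "end_systole"),
               "requires")
})
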