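test_that("bicubic sampling is exact on integers, constants and linear ramps", {
  img <- matrix(runif(30 * 40, 0, 255), 30, 40)
  xs <- c(1, 7, 40); ys <- c(1, 13, 30)
  for (i in seq_along(xs))
    expect_equal(sample_intensity(img, xs[i], ys[i]), img[ys[i], xs[i]],
                 tolerance = 1e-8)

  flat <- matrix(42, 20, 20)
  expect_equal(sample_intensity(flat, c(3.3, 10.71), c(4.9, 15.01)),
               c(42, 42), tolerance = 1e-12)

  # linear reproduction away from the image borders
  ramp <- matrix(rep(1:100, each = 60), 60, 100)  # I = x
  expect_equal(sample_intensity(ramp, 50.25, 30.5), 50.25, tolerance = 1e-9)
  expect_error(sample_intensity(ramp, 0.5, 5), "out-of-bounds")
  expect_error(sample_intensity(ramp, 5, 61), "out-of-bounds")
})

test_that("subset correlation recovers identity, integer and subpixel shifts", {
  dots <- fixture_dots(21, 200, 200)
  ref <- render_dots_mapped(dots, 200, 200)

  id <- correlate_subset(ref, ref, c(100, 100), subset_size = 31)
  expect_true(id$converged)
  expect_equal(c(id$u, id$v), c(0, 0), tolerance = 1e-8)
  expect_equal(id$zncc, 1, tolerance = 1e-12)

  cur_i <- render_dots_mapped(dots, 200, 200, shift_map(3, -2))
  mi <- correlate_subset(ref, cur_i, c(100, 100), subset_size = 31)
  expect_true(mi$converged)
  expect_equal(c(mi$u, mi$v), c(3, -2), tolerance = 0.01)

  cur_s <- render_dots_mapped(dots, 200, 200, shift_map(0.5, 0.25))
  ms <- correlate_subset(ref, cur_s, c(100, 100), subset_size = 31)
  expect_true(ms$converged)
  expect_equal(c(ms$u, ms$v), c(0.5, 0.25), tolerance = 0.05)

  # out-of-bounds warp reports a code instead of throwing
  mo <- correlate_subset(ref, cur_i, c(100, 100),
                         init = list(u = 500, v = 0), subset_size = 31)
  expect_false(mo$converged)
  expect_true(mo$code %in% c(1, 4))
})

test_that("matching is invariant to affine lighting changes", {
  dots <- fixture_dots(22, 200, 200)
  ref <- render_dots_mapped(dots, 200, 200)
  cur <- render_dots_mapped(dots, 200, 200, shift_map(1.25, -0.75))
  m0 <- correlate_subset(ref, cur, c(100, 100), subset_size = 31)
  m1 <- correlate_subset(ref, 1.3 * cur + 20, c(100, 100), subset_size = 31)
  expect_true(m1$converged)
  expect_lt(abs(m1$u - m0$u), 0.01)
  expect_lt(abs(m1$v - m0$v), 0.01)
})

test_that("recovered shape-function gradients match an imposed affine motion", {
  dots <- fixture_dots(23, 240, 240)
  ref <- render_dots_mapped(dots, 240, 240)
  # deform the continuous image by the affine map (cur(x) = ref(W^-1 x))
  A <- rbind(c(1.012, 0.006), c(-0.004, 0.991))
  ctr <- c(120, 120)
  W <- rbind(cbind(A, ctr - A %*% ctr), c(0, 0, 1))
  cur <- cardioDIC:::cpp_warp_homography(ref, solve(W), 240L, 240L)
  m <- correlate_subset(ref, cur, c(120, 120), subset_size = 41)
  expect_true(m$converged)
  expect_lt(max(abs(m$affine -
                      c(A[1, 1] - 1, A[1, 2], A[2, 1], A[2, 2] - 1))), 1e-3)
})

test_that("frame-pair tracking handles stasis, uniform shifts and occlusion", {
  dots <- fixture_dots(24, 220, 220)
  ref <- render_dots_mapped(dots, 220, 220)
  grid <- subset_grid(c(60, 60, 101, 101), c(220, 220), 31, 10)

  same <- track_frame_pair(ref, ref, grid)
  expect_true(all(same$valid))
  expect_equal(max(abs(c(same$u, same$v))), 0, tolerance = 1e-8)

  cur <- render_dots_mapped(dots, 220, 220, shift_map(1, 0))
  sh <- track_frame_pair(ref, cur, grid)
  expect_true(all(sh$valid))
  expect_lt(max(abs(sh$u - 1)), 0.02)
  expect_lt(max(abs(sh$v)), 0.02)

  # blank out the subset of one grid point; the sparse grid keeps the
  # occluded square clear of the neighbours' subsets
  sparse <- subset_grid(c(40, 40, 146, 146), c(220, 220), 31, 35)
  occ <- render_dots_mapped(dots, 220, 220)   # static pair
  mid <- which(sparse$centers[, 1] == 110 & sparse$centers[, 2] == 110)
  occ[(110 - 15):(110 + 15), (110 - 15):(110 + 15)] <- 128
  oc <- track_frame_pair(ref, occ, sparse, search_range = 0)
  expect_false(oc$valid[mid])
  expect_true(all(oc$valid[-mid]))
  expect_lt(max(abs(oc$u[-mid]), abs(oc$v[-mid])), 0.05)
})

test_that("sequence accumulation: statics, drift oracle, and mode agreement", {
  dots <- fixture_dots(25, 200, 200)
  frames <- lapply(1:5, function(k) render_dots_mapped(dots, 200, 200))
  grid <- subset_grid(c(60, 60, 81, 81), c(200, 200), 31, 10)
  f0 <- accumulate_sequence(frames, grid, "incremental")
  expect_equal(max(abs(c(f0$u, f0$v))), 0, tolerance = 1e-8)

  # 20-frame drift of 0.3 px/frame: frame 20 carries 5.7 px
  drift <- lapply(1:20, function(k)
    render_dots_mapped(dots, 200, 200, shift_map(0.3 * (k - 1), 0)))
  fi <- accumulate_sequence(drift, grid, "incremental")
  fr <- accumulate_sequence(drift, grid, "to_reference")
  expect_lt(max(abs(fi$u[20, ] - 5.7)), 0.05)
  expect_lt(max(abs(fr$u[20, ] - 5.7)), 0.05)
  expect_lt(max(abs(fi$u - fr$u), abs(fi$v - fr$v)), 0.05)
  # cumulative quality is the minimum ZNCC along the chain
  expect_true(all(fi$zncc <= 1))
  expect_true(all(diff(fi$zncc[, 1]) <= 1e-12))
  expect_error(accumulate_sequence(drift[1], grid), "invalid-parameter")
})

test_that("tracking a synthetic beat stays within 0.1 px of ground truth", {
  sim <- desk_simulation(n_frames = 18, noise_sigma = 0.5, seed = 9)
  grid <- subset_grid(c(80, 80, 97, 97), c(256, 256), 31, 12)
  fld <- accumulate_sequence(sim$cam1, grid, "to_reference", mm_per_px = 0.1)
  err <- vapply(2:18, function(k) {
    pos <- oracle_positions_px(sim, grid$centers, (k - 1) / 17)
    max(sqrt((fld$u[k, ] - (pos[, 1] - grid$centers[, 1]))^2 +
               (fld$v[k, ] - (pos[, 2] - grid$centers[, 2]))^2))
  }, numeric(1))
  expect_lt(max(err), 0.1)
})

test_that("integer image shifts translate the recovered field exactly", {
  dots <- fixture_dots(26, 200, 200)
  ref <- render_dots_mapped(dots, 200, 200)
  cur <- render_dots_mapped(dots, 200, 200, shift_map(0.8, -0.4))
  grid <- subset_grid(c(70, 70, 61, 61), c(200, 200), 31, 10)
  base <- track_frame_pair(ref, cur, grid)

  dx <- 5; dy <- -3
  shift_img <- function(im) {
    out <- matrix(128, 200, 200)
    src_r <- (1 - min(dy, 0)):(200 - max(dy, 0))
    src_c <- (1 - min(dx, 0)):(200 - max(dx, 0))
    out[src_r + dy, src_c + dx] <- im[src_r, src_c]
    out
  }
  grid2 <- subset_grid(c(70 + dx, 70 + dy, 61, 61), c(200, 200), 31, 10)
  moved <- track_frame_pair(shift_img(ref), shift_img(cur), grid2)
  expect_equal(moved$u, base$u, tolerance = 1e-12)
  expect_equal(moved$v, base$v, tolerance = 1e-12)
})

test_that("noise at 30 dB SNR keeps the displacement error std below 0.05 px", {
  dots <- fixture_dots(27, 220, 220)
  clean <- render_dots_mapped(dots, 220, 220)
  sig <- sd(clean)
  nsd <- sig / 10^(30 / 20)   # 30 dB amplitude SNR
  ref <- clean + withr::with_seed(41, matrix(rnorm(220^2, 0, nsd), 220, 220))
  cur <- render_dots_mapped(dots, 220, 220, shift_map(0.4, 0.2)) +
    withr::with_seed(42, matrix(rnorm(220^2, 0, nsd), 220, 220))
  grid <- subset_grid(c(50, 50, 121, 121), c(220, 220), 31, 10)
  tp <- track_frame_pair(ref, cur, grid)
  expect_gt(nrow(tp), 100)
  expect_lt(sd(tp$u - 0.4), 0.05)
  expect_lt(sd(tp$v - 0.2), 0.05)
})

test_that("quality filtering clamps degenerate thresholds and removes bad points", {
  dots <- fixture_dots(28, 220, 220)
  ref <- render_dots_mapped(dots, 220, 220, noise_sigma = 1, noise_seed = 1)
  cur <- render_dots_mapped(dots, 220, 220, shift_map(0.5, 0),
                            noise_sigma = 1, noise_seed = 2)
  # corrupt the neighbourhood of one grid point in the current frame;
  # the sparse grid keeps other subsets clear of the corruption
  grid <- subset_grid(c(40, 40, 146, 146), c(220, 220), 31, 35)
  bad <- which(grid$centers[, 1] == 110 & grid$centers[, 2] == 110)
  px <- grid$centers[bad, ]
  cur2 <- cur
  cur2[(px[2] - 16):(px[2] + 16), (px[1] - 16):(px[1] + 16)] <-
    withr::with_seed(9, matrix(runif(33^2, 0, 255), 33, 33))
  fld <- accumulate_sequence(list(ref, cur2), grid, "incremental",
                             search_range = 0)

  unfiltered <- quality_filter(fld, 0)       # degenerate, clamped
  expect_identical(unfiltered$valid, fld$valid)

  expect_error(quality_filter(fld, 0.99999), "empty-field")

  suppressMessages(filtered <- quality_filter(fld, 0.8))
  expect_false(all(filtered$valid[2, ]))
  kept <- setdiff(seq_len(nrow(grid$centers)), bad)
  expect_true(all(filtered$valid[2, kept] | !fld$valid[2, kept]))
})
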