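# shared fixtures: all synthetic, generated at test time

# deterministic speckle dot set over a w x h px field (px units)
fixture_dots <- function(seed, width_px, height_px, density_per_mm2 = 2,
                         mm_per_px = 0.1, radius_px = 3) {
  withr::with_seed(seed, {
    n <- round(density_per_mm2 * width_px * height_px * mm_per_px^2)
    list(cx = runif(n, -10, width_px + 10),
         cy = runif(n, -10, height_px + 10),
         r = pmax(rnorm(n, radius_px, radius_px / 5), 1.2))
  })
}

# rasterise the dot set with its centres mapped by `map` (an analytic
# oracle: the deformed image is re-rendered, never resampled)
render_dots_mapped <- function(dots, width_px, height_px, map = identity,
                               blur = 0.8, noise_sigma = 0, noise_seed = 1) {
  p <- map(cbind(dots$cx, dots$cy))
  img <- cardioDIC:::cpp_render_dots(height_px, width_px, p[, 1], p[, 2],
                                     dots$r, 30, 220)
  img <- cardioDIC:::cpp_gauss_blur(img, blur)
  if (noise_sigma > 0)
    img <- img + withr::with_seed(noise_seed,
      matrix(rnorm(length(img), 0, noise_sigma), nrow(img), ncol(img)))
  img
}

shift_map <- function(dx, dy) function(p) cbind(p[, 1] + dx, p[, 2] + dy)

affine_map <- function(A, center, shift = c(0, 0)) {
  function(p) {
    q <- sweep(p, 2, center) %*% t(A)
    sweep(q, 2, center + shift, `+`)
  }
}

# hand-built displacement field for metric-layer tests: fun(x, y, k) must
# return an n x 2 (or n x 3) matrix of px displacements for frame k
make_synth_field <- function(fun, n_frames = 2, image_size = c(200, 200),
                             roi = c(40, 40, 121, 121), step = 10,
                             subset_size = 31, mm_per_px = 0.1,
                             frame_rate = 17) {
  grid <- subset_grid(roi, image_size, subset_size, step)
  np <- nrow(grid$centers)
  u <- matrix(0, n_frames, np); v <- u
  uz <- NULL
  for (k in seq_len(n_frames)) {
    d <- fun(grid$centers[, 1], grid$centers[, 2], k)
    u[k, ] <- d[, 1]; v[k, ] <- d[, 2]
    if (ncol(d) >= 3) {
      if (is.null(uz)) uz <- matrix(0, n_frames, np)
      uz[k, ] <- d[, 3]
    }
  }
  f <- structure(list(u = u, v = v,
                      zncc = matrix(1, n_frames, np),
                      valid = matrix(TRUE, n_frames, np),
                      grid = grid, mode = "incremental",
                      reference_frame = 1L, mm_per_px = mm_per_px,
                      frame_rate = frame_rate,
                      time = (seq_len(n_frames) - 1) / frame_rate),
                 class = "displacement_field")
  if (!is.null(uz)) {
    f$ux_mm <- u * mm_per_px; f$uy_mm <- v * mm_per_px
    f$uz_mm <- uz * mm_per_px
  }
  f
}

make_beats <- function(boundaries) {
  structure(list(intervals = cbind(start = boundaries[-length(boundaries)],
                                   end = boundaries[-1]),
                 boundaries = boundaries,
                 prominences = numeric(0)),
            class = "beat_segmentation")
}

# small desk-scale stereo simulation shared across tests
desk_simulation <- function(n_frames = 18, frame_rate = 17,
                            image_px = 256, patch_mm = 16,
                            translation = c(3, -2, 5),
                            contraction = 0.2, heart_rate = 60,
                            respiration_depth = 0, noise_sigma = 1,
                            seed = 5, vergence_deg = 15) {
  pp <- speckle_pattern_params(noise_sigma = noise_sigma, seed = seed)
  mot <- motion_model_params(heart_rate = heart_rate,
                             contraction_amplitude = contraction,
                             translation_amplitude = translation,
                             respiration_mod_depth = respiration_depth,
                             seed = seed)
  rig <- stereo_rig(c(image_px, image_px), 0.1, 1000, vergence_deg)
  sim <- generate_stereo_sequences(pp, mot, rig, n_frames, frame_rate,
                                   patch_size_mm = c(patch_mm, patch_mm),
                                   mm_per_px = 0.1)
  c(sim, list(motion = mot, rig = rig, pattern = pp))
}

# analytic pixel position of camera-1 grid points at time t (projection of
# the exactly known surface motion; independent of the tracker)
oracle_positions_px <- function(sim, centers_px, t) {
  H0 <- cardioDIC:::plane_homography(sim$rig[[1]]$projection, 0)
  gmm <- cardioDIC:::apply_h(solve(H0), centers_px)
  ugt <- true_displacement(sim$motion, gmm, t)
  m <- cardioDIC:::motion_affine(sim$motion, t)
  Hk <- cardioDIC:::plane_homography(sim$rig[[1]]$projection, m$uz)
  cardioDIC:::apply_h(Hk, cbind(gmm[, 1] + ugt[, 1], gmm[, 2] + ugt[, 2]))
}
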