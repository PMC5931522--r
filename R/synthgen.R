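#' Render a random speckle pattern
#'
#' Rasterises anti-aliased dark dots on a light background, applies Gaussian
#' blur and (optionally) additive Gaussian noise.  Dot count is Poisson with
#' mean `dot_density * area`; placement is uniform.  Fully reproducible for
#' a fixed seed.
#'
#' @param params a [speckle_pattern_params()] object.
#' @param width_px,height_px image dimensions, px.
#' @param mm_per_px physical pixel size, mm.
#' @param add_noise add the per-image noise stage (disable when the pattern
#'   serves as a clean reference for warping).
#' @return numeric matrix `height_px x width_px` of gray levels, with
#'   attributes `mm_per_px` and `n_dots`.
#' @export
render_speckle_pattern <- function(params, width_px, height_px, mm_per_px,
                                   add_noise = TRUE) {
  if (!inherits(params, "speckle_pattern_params"))
    stopf("invalid-parameter: `params` must be speckle_pattern_params")
  check_scalar(width_px, "width_px", lower = 1)
  check_scalar(height_px, "height_px", lower = 1)
  check_scalar(mm_per_px, "mm_per_px", lower = 0, strict_lower = TRUE)
  area_mm2 <- width_px * height_px * mm_per_px^2
  img <- with_seed(params$seed, {
    n_dots <- rpois(1, params$dot_density * area_mm2)
    if (n_dots > 0) {
      cx <- runif(n_dots, 0.5, width_px + 0.5)
      cy <- runif(n_dots, 0.5, height_px + 0.5)
      r <- pmax(rnorm(n_dots, params$dot_radius_mean, params$dot_radius_sd),
                0.25 * params$dot_radius_mean) / mm_per_px
      im <- cpp_render_dots(as.integer(height_px), as.integer(width_px),
                            cx, cy, r,
                            params$dot_intensity, params$background_intensity)
    } else {
      im <- matrix(params$background_intensity, height_px, width_px)
    }
    im <- cpp_gauss_blur(im, params$blur_sigma)
    if (add_noise && params$noise_sigma > 0)
      im <- im + matrix(rnorm(length(im), 0, params$noise_sigma),
                        nrow(im), ncol(im))
    attr(im, "n_dots") <- n_dots
    im
  })
  attr(img, "mm_per_px") <- mm_per_px
  img
}

#' Unit beat waveform
#'
#' Piecewise-cosine contraction waveform, range `[0, 1]`: 0 at end-diastole
#' (reference), 1 at end-systole.  Phases: cosine ramp up over the systolic
#' fraction, cosine recovery by `early_recovery_ratio` over the
#' early-diastolic fraction, diastasis plateau, and a final cosine ramp to 0
#' over the atrial fraction.  Continuous and periodic in the beat period.
#'
#' @param params a [motion_model_params()] object.
#' @param t time(s), s.
#' @return numeric vector of waveform values in `[0, 1]`.
#' @export
beat_waveform <- function(params, t) {
  if (any(t < 0)) stopf("invalid-parameter: t must be >= 0")
  Tb <- 60 / params$heart_rate
  tau <- (t %% Tb) / Tb
  fs <- params$systole_fraction
  fe <- params$early_diastole_fraction
  fa <- params$atrial_fraction
  re <- params$early_recovery_ratio
  w <- numeric(length(tau))
  ramp <- function(x) (1 - cos(pi * pmin(pmax(x, 0), 1))) / 2  # 0 -> 1
  i1 <- tau < fs
  w[i1] <- ramp(tau[i1] / fs)
  i2 <- !i1 & tau < fs + fe
  w[i2] <- 1 - re * ramp((tau[i2] - fs) / fe)
  i3 <- !i1 & !i2 & tau < 1 - fa
  w[i3] <- 1 - re
  i4 <- !i1 & !i2 & !i3
  w[i4] <- (1 - re) * (1 - ramp((tau[i4] - (1 - fa)) / fa))
  w
}

#' Cardiac contraction scale factor
#'
#' `c(t) = 1 - a * w(t)` where `w` is the unit beat waveform and `a` the
#' contraction amplitude: 1 at end-diastole (the reference state), `1 - a`
#' at end-systole, passing through the plateau at `1 - a + re * a` during
#' diastasis.
#'
#' @inheritParams beat_waveform
#' @return numeric vector of scale factors in `[1 - a, 1]`.
#' @export
cardiac_scale <- function(params, t) {
  1 - params$contraction_amplitude * beat_waveform(params, t)
}

#' Respiration amplitude-modulation envelope
#'
#' `1 + depth * sin(2 pi f_resp t)`, the slow multiplicative modulation of
#' the whole cardiac displacement imposed by the respirator.
#'
#' @inheritParams beat_waveform
#' @return numeric vector of envelope values.
#' @export
respiration_envelope <- function(params, t) {
  1 + params$respiration_mod_depth *
    sin(2 * pi * params$respiration_rate / 60 * t)
}

# The full in-plane affine map and out-of-plane offset at time t:
#   x(X) = center + A (X - center) + b,   z = uz
# with A = I + M(t) diag(ax, ay) (c(t) - 1) and b = M(t) w(t) T_xy.
motion_affine <- function(params, t) {
  w <- beat_waveform(params, t)
  cc <- 1 - params$contraction_amplitude * w
  M <- respiration_envelope(params, t)
  sx <- 1 + M * params$anisotropy[1] * (cc - 1)
  sy <- 1 + M * params$anisotropy[2] * (cc - 1)
  bx <- M * w * params$translation_amplitude[1]
  by <- M * w * params$translation_amplitude[2]
  uz <- M * w * params$translation_amplitude[3]
  list(sx = sx, sy = sy, bx = bx, by = by, uz = uz, c = cc, w = w, M = M)
}

#' Ground-truth surface displacement
#'
#' Analytic displacement of a material point: superposition of rigid-body
#' translation and homogeneous contraction about the model centre, the
#' whole amplitude modulated by the respiration envelope; the z component
#' is the out-of-plane translation.  `u(X, 0) = 0` for every `X`.
#'
#' @param params a [motion_model_params()] object.
#' @param X in-plane material point(s), mm: length-2 vector or `n x 2`
#'   matrix (world coordinates on the surface patch).
#' @param t a single time, s.
#' @return `n x 3` matrix of displacements `(u_x, u_y, u_z)` in mm.
#' @export
true_displacement <- function(params, X, t) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 2)
  stopifnot(ncol(X) >= 2, length(t) == 1L)
  m <- motion_affine(params, t)
  dx <- X[, 1] - params$center[1]
  dy <- X[, 2] - params$center[2]
  cbind(u_x = m$bx + (m$sx - 1) * dx,
        u_y = m$by + (m$sy - 1) * dy,
        u_z = rep(m$uz, nrow(X)))
}

#' Ground-truth Green-Lagrange surface strain
#'
#' For the homogeneous (affine) motion model the in-plane deformation
#' gradient is the diagonal matrix `diag(sx, sy)` and the strain tensor is
#' spatially constant.
#'
#' @inheritParams beat_waveform
#' @return data.frame with columns `t, Exx, Eyy, Exy, stretch_x, stretch_y`.
#' @export
true_strain <- function(params, t) {
  m <- motion_affine(params, t)
  data.frame(t = t,
             Exx = (m$sx^2 - 1) / 2,
             Eyy = (m$sy^2 - 1) / 2,
             Exy = 0,
             stretch_x = m$sx,
             stretch_y = m$sy)
}

# homography mm-world-plane(z = h) -> image px for a 3x4 camera P
plane_homography <- function(P, h = 0) {
  cbind(P[, 1], P[, 2], h * P[, 3] + P[, 4])
}

# affine map material mm -> deformed mm as a 3x3 homogeneous matrix
affine_h <- function(m, center) {
  rbind(c(m$sx, 0, center[1] * (1 - m$sx) + m$bx),
        c(0, m$sy, center[2] * (1 - m$sy) + m$by),
        c(0, 0, 1))
}

apply_h <- function(H, xy) {
  p <- H %*% rbind(t(xy), 1)
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}

#' Generate a synthetic stereo beating-heart sequence
#'
#' Renders the motion model through two calibrated pinhole cameras by
#' inverse-mapping every output pixel through the (exactly known) surface
#' motion and sampling the clean reference speckle pattern bicubically;
#' per-frame sensor noise is added afterwards.  Ground truth (displacement,
#' strain, extensometer length) is recorded on the grid the tracker will
#' use.
#'
#' @param pattern a [speckle_pattern_params()] object.
#' @param motion a [motion_model_params()] object.
#' @param cams list of two [camera_model()] objects (see [stereo_rig()]).
#' @param n_frames number of frames per camera.
#' @param frame_rate acquisition rate, Hz.
#' @param patch_size_mm physical extent `(width, height)` of the speckled
#'   surface patch, mm, centred on the world origin in the plane z = 0.
#' @param margin_mm width of additional speckled surface rendered around
#'   the nominal patch (the tissue continues beyond the analysed patch, so
#'   subsets near the patch edge stay textured under motion), mm.
#' @param mm_per_px sampling pitch of the reference pattern, mm.
#' @param gt_points_px optional `n x 2` matrix of camera-1 reference-image
#'   pixel positions at which ground truth is recorded; default: a 10 px
#'   lattice over the central 80% of the patch.
#' @param extensometer_px optional `2 x 2` matrix (rows = endpoints) of the
#'   virtual extensometer in camera-1 reference px; default: a vertical
#'   line through the patch centre spanning 60% of the patch height.
#' @return list with `cam1`, `cam2` ([image_sequence()]) and `ground_truth`
#'   (class `ground_truth`): per-frame displacement `u` (`n_frames x n_pts x
#'   3`, mm), strain table, extensometer length `L_mm`, scale `c`, waveform
#'   `w`, envelope `M`, the ground-truth grid in camera-1 px and material
#'   mm, and the pattern/camera geometry.
#' @export
generate_stereo_sequences <- function(pattern, motion, cams,
                                      n_frames, frame_rate,
                                      patch_size_mm = c(32, 32),
                                      margin_mm = 6,
                                      mm_per_px = 0.1,
                                      gt_points_px = NULL,
                                      extensometer_px = NULL) {
  stopifnot(inherits(pattern, "speckle_pattern_params"),
            inherits(motion, "motion_model_params"))
  if (length(cams) != 2L)
    stopf("invalid-parameter: `cams` must list exactly two cameras")
  check_scalar(n_frames, "n_frames", lower = 2)
  check_scalar(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)

  pw <- round((patch_size_mm[1] + 2 * margin_mm) / mm_per_px)
  ph <- round((patch_size_mm[2] + 2 * margin_mm) / mm_per_px)
  ref_pattern <- render_speckle_pattern(pattern, pw, ph, mm_per_px,
                                        add_noise = FALSE)
  # mm -> pattern px (pattern centred on the world origin)
  S <- rbind(c(1 / mm_per_px, 0, (pw + 1) / 2),
             c(0, 1 / mm_per_px, (ph + 1) / 2),
             c(0, 0, 1))

  times <- (seq_len(n_frames) - 1) / frame_rate
  corners_mm <- cbind(c(-1, 1, 1, -1) * patch_size_mm[1] / 2,
                      c(-1, -1, 1, 1) * patch_size_mm[2] / 2)

  H0 <- lapply(cams, function(cm) plane_homography(cm$projection, 0))

  frames1 <- vector("list", n_frames)
  frames2 <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    m <- motion_affine(motion, times[k])
    Aff <- affine_h(m, motion$center)
    def_corners <- apply_h(Aff, corners_mm)
    for (ci in 1:2) {
      cm <- cams[[ci]]
      Hk <- plane_homography(cm$projection, m$uz)
      cpx <- apply_h(Hk, def_corners)
      if (any(cpx[, 1] < 1) || any(cpx[, 1] > cm$image_size[1]) ||
          any(cpx[, 2] < 1) || any(cpx[, 2] > cm$image_size[2]))
        stopf("out-of-view: surface leaves camera %d's field of view at frame %d",
              ci, k)
      # output px -> pattern px
      W <- S %*% solve(Aff) %*% solve(Hk)
      img <- cpp_warp_homography(ref_pattern, W,
                                 as.integer(cm$image_size[2]),
                                 as.integer(cm$image_size[1]))
      if (pattern$noise_sigma > 0)
        img <- img + with_seed(pattern$seed + 7919L * ci + k,
                               matrix(rnorm(length(img), 0, pattern$noise_sigma),
                                      nrow(img), ncol(img)))
      if (ci == 1) frames1[[k]] <- img else frames2[[k]] <- img
    }
  }

  # ground-truth grid: default 10 px lattice over central 80% of the patch
  # as seen by camera 1 in the reference frame
  ref_corner_px <- apply_h(H0[[1]], corners_mm)
  if (is.null(gt_points_px)) {
    x0 <- min(ref_corner_px[, 1]); x1 <- max(ref_corner_px[, 1])
    y0 <- min(ref_corner_px[, 2]); y1 <- max(ref_corner_px[, 2])
    mx <- 0.1 * (x1 - x0); my <- 0.1 * (y1 - y0)
    gx <- seq(ceiling(x0 + mx), floor(x1 - mx), by = 10)
    gy <- seq(ceiling(y0 + my), floor(y1 - my), by = 10)
    gt_points_px <- as.matrix(expand.grid(x = gx, y = gy))
  }
  # camera-1 reference px -> material mm
  to_mm <- solve(H0[[1]])
  grid_mm <- apply_h(to_mm, gt_points_px)

  if (is.null(extensometer_px)) {
    ctr <- apply_h(H0[[1]], matrix(c(0, 0), 1))
    half_len <- 0.3 * abs(diff(range(ref_corner_px[, 2])))
    extensometer_px <- rbind(c(ctr[1], ctr[2] - half_len),
                             c(ctr[1], ctr[2] + half_len))
  }
  ext_mm <- apply_h(to_mm, extensometer_px)

  np <- nrow(grid_mm)
  u <- array(0, c(n_frames, np, 3),
             dimnames = list(NULL, NULL, c("u_x", "u_y", "u_z")))
  L_mm <- numeric(n_frames)
  strain <- true_strain(motion, times)
  for (k in seq_len(n_frames)) {
    u[k, , ] <- true_displacement(motion, grid_mm, times[k])
    m <- motion_affine(motion, times[k])
    d <- c(m$sx * (ext_mm[1, 1] - ext_mm[2, 1]),
           m$sy * (ext_mm[1, 2] - ext_mm[2, 2]))
    L_mm[k] <- sqrt(sum(d^2))
  }
  m0 <- motion_affine(motion, times)

  gt <- structure(list(time = times,
                       grid_px = gt_points_px,
                       grid_mm = grid_mm,
                       u = u,
                       strain = strain,
                       L_mm = L_mm,
                       c = m0$c, w = m0$w, M = m0$M,
                       extensometer_px = extensometer_px,
                       extensometer_mm = ext_mm,
                       mm_per_px = mm_per_px,
                       patch_size_mm = patch_size_mm,
                       motion = motion,
                       cams = cams),
                  class = "ground_truth")

  list(cam1 = image_sequence(frames1, frame_rate, bit_depth = pattern$bit_depth,
                             camera_id = "cam1"),
       cam2 = image_sequence(frames2, frame_rate, bit_depth = pattern$bit_depth,
                             camera_id = "cam2"),
       ground_truth = gt)
}

#' Synthetic 3D calibration target
#'
#' Points on two inclined planes of a chevron-style target, the standard
#' way to obtain non-coplanar world points from a single rigid object.
#'
#' @param n_per_plane points per plane (arranged in a near-square grid).
#' @param extent_mm in-plane extent of each grid, mm.
#' @param depth_mm separation of the two planes along z, mm.
#' @return `n x 3` matrix of world points, mm.
#' @export
calibration_target <- function(n_per_plane = 10, extent_mm = 40,
                               depth_mm = 20) {
  nside <- ceiling(sqrt(n_per_plane))
  g <- seq(-extent_mm / 2, extent_mm / 2, length.out = nside)
  pts <- as.matrix(expand.grid(X = g, Y = g))[seq_len(n_per_plane), , drop = FALSE]
  rbind(cbind(pts, Z = 0),
        cbind(pts + extent_mm / (2 * nside), Z = depth_mm))
}

#' Render calibration views of a 3D target
#'
#' Projects known world points through both cameras, optionally perturbing
#' the image points with Gaussian pixel noise, and returns the
#' correspondence table used for calibration.
#'
#' @param world_points `n x 3` matrix of target points, mm (at least 6,
#'   non-coplanar).
#' @param cams list of two [camera_model()] objects.
#' @param pixel_noise_sigma Gaussian noise applied to image points, px.
#' @param seed RNG seed for the noise.
#' @return data.frame: `point_id, X_mm, Y_mm, Z_mm, cam1_x_px, cam1_y_px,
#'   cam2_x_px, cam2_y_px`.
#' @export
render_calibration_views <- function(world_points, cams,
                                     pixel_noise_sigma = 0, seed = 1L) {
  world_points <- as.matrix(world_points)
  check_target_geometry(world_points)
  n <- nrow(world_points)
  out <- data.frame(point_id = seq_len(n),
                    X_mm = world_points[, 1],
                    Y_mm = world_points[, 2],
                    Z_mm = world_points[, 3])
  noise <- if (pixel_noise_sigma > 0)
    with_seed(seed, matrix(rnorm(4 * n, 0, pixel_noise_sigma), n, 4))
  else matrix(0, n, 4)
  for (ci in 1:2) {
    px <- t(apply(world_points, 1, function(X) reproject(cams[[ci]], X)))
    out[[paste0("cam", ci, "_x_px")]] <- px[, 1] + noise[, 2 * ci - 1]
    out[[paste0("cam", ci, "_y_px")]] <- px[, 2] + noise[, 2 * ci]
  }
  out
}

# shared degenerate-target check: >= 6 points, genuinely 3D
check_target_geometry <- function(world_points) {
  if (nrow(world_points) < 6)
    stopf("insufficient-points: calibration needs >= 6 points, got %d",
          nrow(world_points))
  ctr <- scale(world_points, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * sv[1])
    stopf("degenerate-target: calibration points are coplanar")
  invisible(TRUE)
}
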