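#' Pinhole camera model
#'
#' A camera is a rank-3 homogeneous `3 x 4` projection matrix mapping world
#' coordinates (mm, the calibration-target frame) to image pixels.  Lens
#' distortion is not modelled.
#'
#' @param projection `3 x 4` numeric matrix.
#' @param image_size image dimensions `c(width, height)`, px.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(projection, image_size) {
  projection <- as.matrix(projection)
  if (!all(dim(projection) == c(3, 4)) || !all(is.finite(projection)))
    stopf("invalid-parameter: projection must be a finite 3 x 4 matrix")
  if (qr(projection)$rank < 3)
    stopf("invalid-parameter: projection matrix must have rank 3")
  structure(list(projection = projection,
                 image_size = as.numeric(image_size)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Pinhole camera, image %g x %g px\n",
              x$image_size[1], x$image_size[2]))
  print(signif(x$projection, 5))
  invisible(x)
}

#' Two-camera rig viewing the surface patch
#'
#' Builds the stereo pair used by the synthetic generator: camera 1
#' fronto-parallel to the patch plane z = 0 at the working distance (so one
#' pixel subtends `mm_per_px` mm on that plane), camera 2 converged on the
#' patch centre from an angle, emulating the slanted two-camera view of an
#' operating-theatre installation.
#'
#' @param image_size_px image dimensions `c(width, height)`, px.
#' @param mm_per_px pixel footprint of camera 1 on the patch plane, mm.
#' @param distance_mm working distance, mm.
#' @param vergence_deg angle of camera 2 about the vertical axis, degrees.
#' @return list of two [camera_model()] objects.
#' @export
stereo_rig <- function(image_size_px = c(512, 512), mm_per_px = 0.1,
                       distance_mm = 1000, vergence_deg = 15) {
  f <- distance_mm / mm_per_px
  cx <- (image_size_px[1] + 1) / 2
  cy <- (image_size_px[2] + 1) / 2
  K <- rbind(c(f, 0, cx), c(0, f, cy), c(0, 0, 1))
  P1 <- K %*% cbind(diag(3), c(0, 0, distance_mm))
  th <- vergence_deg * pi / 180
  R2 <- rbind(c(cos(th), 0, -sin(th)),
              c(0, 1, 0),
              c(sin(th), 0, cos(th)))
  P2 <- K %*% cbind(R2, c(0, 0, distance_mm))
  list(camera_model(P1, image_size_px), camera_model(P2, image_size_px))
}

#' Project a world point through a camera
#'
#' Homogeneous projection followed by perspective division.
#'
#' @param camera a [camera_model()].
#' @param world_point length-3 world point, mm.
#' @return `c(x, y)` in px.
#' @export
reproject <- function(camera, world_point) {
  p <- camera$projection %*% c(world_point, 1)
  if (abs(p[3]) < 1e-12)
    stopf("projection-singularity: point lies on the camera's principal plane")
  c(p[1] / p[3], p[2] / p[3])
}

# Hartley-normalised direct linear transform for one camera
dlt_solve <- function(world, img) {
  n <- nrow(world)
  # normalisation for conditioning
  cw <- colMeans(world); ci <- colMeans(img)
  sw <- sqrt(3) / mean(sqrt(rowSums(sweep(world, 2, cw)^2)))
  si <- sqrt(2) / mean(sqrt(rowSums(sweep(img, 2, ci)^2)))
  Tw <- rbind(cbind(diag(sw, 3), -sw * cw), c(0, 0, 0, 1))
  Ti <- rbind(cbind(diag(si, 2), -si * ci), c(0, 0, 1))
  Wn <- t(Tw %*% rbind(t(world), 1))
  In <- t(Ti %*% rbind(t(img), 1))
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- Wn[i, ]; x <- In[i, 1]; y <- In[i, 2]
    A[2 * i - 1, ] <- c(X, rep(0, 4), -x * X)
    A[2 * i, ]     <- c(rep(0, 4), X, -y * X)
  }
  v <- svd(A, nu = 0)$v[, 12]
  Pn <- matrix(v, 3, 4, byrow = TRUE)
  P <- solve(Ti) %*% Pn %*% Tw
  P / sqrt(sum(P^2))
}

#' Calibrate a camera from a 3D target (DLT + refinement)
#'
#' Direct linear transform on at least six non-coplanar world-image
#' correspondences, refined by quasi-Newton minimisation of the
#' reprojection error.  The calibration error is the root mean square of
#' the per-point distances between reprojected and measured image
#' positions.
#'
#' @param world_points `n x 3` matrix, mm.
#' @param image_points `n x 2` matrix, px.
#' @param image_size image dimensions passed to the resulting camera.
#' @return An object of class `calibration_result`: `camera`, `rms_error`
#'   (px), `n_points`, `per_point_residuals` (px).
#' @export
calibrate_dlt <- function(world_points, image_points,
                          image_size = c(NA_real_, NA_real_)) {
  world_points <- as.matrix(world_points)
  image_points <- as.matrix(image_points)
  if (nrow(world_points) != nrow(image_points))
    stopf("invalid-parameter: correspondence counts differ")
  check_target_geometry(world_points)
  n <- nrow(world_points)

  P <- dlt_solve(world_points, image_points)
  sse <- function(p) {
    Pm <- matrix(p, 3, 4)
    pr <- Pm %*% rbind(t(world_points), 1)
    dx <- pr[1, ] / pr[3, ] - image_points[, 1]
    dy <- pr[2, ] / pr[3, ] - image_points[, 2]
    sum(dx^2 + dy^2)
  }
  opt <- optim(as.vector(P), sse, method = "BFGS",
               control = list(maxit = 300, reltol = 1e-14))
  P <- matrix(opt$par, 3, 4)
  P <- P / sqrt(sum(P^2))

  pr <- P %*% rbind(t(world_points), 1)
  res <- sqrt((pr[1, ] / pr[3, ] - image_points[, 1])^2 +
              (pr[2, ] / pr[3, ] - image_points[, 2])^2)
  structure(list(camera = camera_model(P, image_size),
                 rms_error = sqrt(mean(res^2)),
                 n_points = n,
                 per_point_residuals = res),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: %d points, RMS error %.4g px\n",
              x$n_points, x$rms_error))
  invisible(x)
}

#' Triangulate a stereo correspondence
#'
#' Homogeneous linear least-squares (DLT) triangulation of one point seen
#' in both views.
#'
#' @param cam1,cam2 [camera_model()] objects (distinct).
#' @param px1,px2 image points `c(x, y)` in each view.
#' @return list: `world_point` (mm), `reprojection_residual` (mean px error
#'   over both views).
#' @export
triangulate_pair <- function(cam1, cam2, px1, px2) {
  if (max(abs(cam1$projection / sqrt(sum(cam1$projection^2)) -
              cam2$projection / sqrt(sum(cam2$projection^2)))) < 1e-12)
    stopf("ill-conditioned: cameras are identical")
  A <- triangulation_rows(cam1$projection, px1, cam2$projection, px2)
  sv <- svd(A)
  if (sv$d[1] / max(sv$d[4], .Machine$double.xmin) > 1e10 &&
      sv$d[1] / max(sv$d[3], .Machine$double.xmin) > 1e10)
    stopf("ill-conditioned: triangulation rays are near-parallel")
  Xh <- sv$v[, 4]
  X <- Xh[1:3] / Xh[4]
  r1 <- sqrt(sum((reproject(cam1, X) - px1)^2))
  r2 <- sqrt(sum((reproject(cam2, X) - px2)^2))
  list(world_point = X, reprojection_residual = (r1 + r2) / 2)
}

triangulation_rows <- function(P1, px1, P2, px2) {
  rbind(px1[1] * P1[3, ] - P1[1, ],
        px1[2] * P1[3, ] - P1[2, ],
        px2[1] * P2[3, ] - P2[1, ],
        px2[2] * P2[3, ] - P2[2, ])
}

# fast path used by lift_fields_to_3d: triangulate many points without the
# per-call conditioning diagnostics
triangulate_many <- function(P1, P2, x1, y1, x2, y2) {
  n <- length(x1)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (is.na(x1[i]) || is.na(x2[i])) next
    A <- rbind(x1[i] * P1[3, ] - P1[1, ],
               y1[i] * P1[3, ] - P1[2, ],
               x2[i] * P2[3, ] - P2[1, ],
               y2[i] * P2[3, ] - P2[2, ])
    # normal-equation solve of the homogeneous system via its 4x4 eigenproblem
    Xh <- svd(A, nu = 0)$v[, 4]
    out[i, ] <- Xh[1:3] / Xh[4]
  }
  out
}

#' Cross-camera correspondence of the reference frame
#'
#' Locates every left-grid subset in the right reference image: seeded from
#' the projected patch-plane geometry when cameras are supplied (otherwise
#' from zero disparity), located by integer ZNCC search and refined to
#' subpixel accuracy with the affine subset solver.
#'
#' @param left_ref,right_ref reference-frame images of the two cameras.
#' @param grid [subset_grid()] on the left reference image.
#' @param cam_left,cam_right optional [camera_model()] pair used to seed
#'   the search via the z = 0 patch plane.
#' @param search_range integer search half-width around the seed, px.
#' @return data.frame: `point_id, x_left, y_left, x_right, y_right, zncc,
#'   valid`.
#' @export
stereo_correspond <- function(left_ref, right_ref, grid,
                              cam_left = NULL, cam_right = NULL,
                              search_range = 10) {
  n <- nrow(grid$centers)
  seed <- matrix(0, n, 2)
  if (!is.null(cam_left) && !is.null(cam_right)) {
    Hl <- plane_homography(cam_left$projection, 0)
    Hr <- plane_homography(cam_right$projection, 0)
    right_px <- apply_h(Hr %*% solve(Hl), grid$centers)
    seed <- right_px - grid$centers
  }
  res <- cpp_track_points(left_ref, right_ref,
                          grid$centers[, 1], grid$centers[, 2],
                          as.integer(grid$half),
                          seed[, 1], seed[, 2], as.integer(search_range))
  valid <- res[, 8] == 1
  if (mean(valid) < 0.5)
    stopf("correspondence-collapse: only %d of %d subsets matched across cameras",
          sum(valid), n)
  data.frame(point_id = seq_len(n),
             x_left = grid$centers[, 1], y_left = grid$centers[, 2],
             x_right = ifelse(valid, grid$centers[, 1] + res[, 1], NA_real_),
             y_right = ifelse(valid, grid$centers[, 2] + res[, 2], NA_real_),
             zncc = ifelse(valid, res[, 7], NA_real_),
             valid = valid)
}

#' Lift two 2D displacement fields to 3D by triangulation
#'
#' Per frame, each grid point's left and right image positions are
#' triangulated; the 3D displacement is the triangulated position minus the
#' reference-frame triangulated position.  A point is invalid wherever any
#' input (either field or the correspondence) is invalid.
#'
#' @param field_left,field_right `displacement_field`s from the two
#'   cameras, sharing grid layout and frame count.
#' @param disparity output of [stereo_correspond()].
#' @param cam_left,cam_right calibrated [camera_model()] pair.
#' @return the left `displacement_field` augmented with `ux_mm`, `uy_mm`,
#'   `uz_mm` (`n_frames x n_points`, world mm) and `X0_mm` (reference 3D
#'   positions).
#' @export
lift_fields_to_3d <- function(field_left, field_right, disparity,
                              cam_left, cam_right) {
  nf <- nrow(field_left$u); np <- ncol(field_left$u)
  if (nrow(field_right$u) != nf || ncol(field_right$u) != np ||
      !isTRUE(all.equal(field_left$grid$step, field_right$grid$step)))
    stopf("incompatible-fields: left/right grids or frame counts differ")
  P1 <- cam_left$projection; P2 <- cam_right$projection
  xl0 <- field_left$grid$centers[, 1]; yl0 <- field_left$grid$centers[, 2]
  xr0 <- disparity$x_right; yr0 <- disparity$y_right

  X0 <- triangulate_many(P1, P2, xl0, yl0, xr0, yr0)
  ux <- matrix(NA_real_, nf, np); uy <- ux; uz <- ux
  valid <- field_left$valid & field_right$valid &
    matrix(disparity$valid, nf, np, byrow = TRUE)
  for (k in seq_len(nf)) {
    ok <- valid[k, ]
    if (!any(ok)) next
    Xk <- triangulate_many(P1, P2,
                           xl0[ok] + field_left$u[k, ok],
                           yl0[ok] + field_left$v[k, ok],
                           xr0[ok] + field_right$u[k, ok],
                           yr0[ok] + field_right$v[k, ok])
    ux[k, ok] <- Xk[, 1] - X0[ok, 1]
    uy[k, ok] <- Xk[, 2] - X0[ok, 2]
    uz[k, ok] <- Xk[, 3] - X0[ok, 3]
  }
  out <- field_left
  out$ux_mm <- ux; out$uy_mm <- uy; out$uz_mm <- uz
  out$valid <- valid
  out$X0_mm <- X0
  out
}
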