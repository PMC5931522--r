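#' Measurement grid of correlation subsets
#'
#' A regular lattice of subset centres with spacing `step` inside a region
#' of interest, every subset lying fully inside the image.
#'
#' @param roi region of interest `c(x0, y0, width, height)` in reference
#'   image px.
#' @param image_size image dimensions `c(width, height)`, px.
#' @param subset_size odd subset edge length, px (>= 11; default 79, the
#'   production setting; tests typically use 31).
#' @param step lattice spacing, px (default 10).
#' @return An object of class `subset_grid` with `centers` (`n x 2`),
#'   `subset_size`, `half`, `step`, `roi`.
#' @export
subset_grid <- function(roi, image_size, subset_size = 79, step = 10) {
  if (length(roi) != 4 || any(!is.finite(roi)))
    stopf("invalid-parameter: roi must be c(x0, y0, width, height)")
  if (subset_size %% 2 != 1 || subset_size < 11)
    stopf("invalid-parameter: subset_size must be odd and >= 11")
  check_scalar(step, "step", lower = 1)
  half <- (subset_size - 1) / 2
  # margin 2 px for the bicubic support
  lo_x <- max(roi[1], half + 3)
  hi_x <- min(roi[1] + roi[3] - 1, image_size[1] - half - 2)
  lo_y <- max(roi[2], half + 3)
  hi_y <- min(roi[2] + roi[4] - 1, image_size[2] - half - 2)
  if (lo_x > hi_x || lo_y > hi_y)
    stopf("invalid-parameter: roi leaves no room for subsets of size %d",
          subset_size)
  gx <- seq(lo_x, hi_x, by = step)
  gy <- seq(lo_y, hi_y, by = step)
  centers <- as.matrix(expand.grid(x = gx, y = gy))
  structure(list(centers = centers, subset_size = subset_size,
                 half = half, step = step, roi = roi,
                 nx = length(gx), ny = length(gy),
                 image_size = image_size),
            class = "subset_grid")
}

#' @export
print.subset_grid <- function(x, ...) {
  cat(sprintf("Subset grid: %d points (%d x %d), subset %d px, step %d px\n",
              nrow(x$centers), x$nx, x$ny, x$subset_size, x$step))
  invisible(x)
}

#' Sample image intensity at real-valued coordinates
#'
#' Bicubic (Keys) interpolation; exact at integer coordinates and exact for
#' linear intensity ramps.
#'
#' @param image numeric matrix `[row, col]`.
#' @param x,y coordinates (x = column, y = row, 1-based pixel centres).
#' @return interpolated intensities.
#' @export
sample_intensity <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  if (any(x < 1 | x > nc | y < 1 | y > nr))
    stopf("out-of-bounds: sample coordinates outside [1, %d] x [1, %d]",
          nc, nr)
  cpp_interp_image(image, x, y)
}

#' Correlate one subset between two images
#'
#' First-order (affine shape function) inverse-compositional Gauss-Newton
#' minimisation of the zero-normalised SSD criterion, reporting the ZNCC of
#' the converged warp.  Divergence or an out-of-bounds warp is reported via
#' `converged = FALSE` and a diagnostic code, never an exception.
#'
#' @param ref_image,cur_image numeric matrices.
#' @param center subset centre `c(x, y)` in `ref_image` px (may be
#'   fractional).
#' @param init initial guess: list with `u`, `v` (px) and optionally
#'   `affine` (the four shape-function gradients `ux, uy, vx, vy`).
#' @param subset_size odd subset size, px.
#' @param tol convergence threshold on the parameter update norm, px.
#' @param max_iter iteration cap.
#' @return list: `u`, `v` (px), `affine` (length 4), `zncc`, `converged`,
#'   `iterations`, `code` (0 ok, 1 out-of-bounds, 2 flat subset, 3 no
#'   convergence, 4 diverged).
#' @export
correlate_subset <- function(ref_image, cur_image, center,
                             init = list(u = 0, v = 0),
                             subset_size = 79, tol = 1e-4, max_iter = 50) {
  half <- (subset_size - 1) / 2
  aff <- init$affine %||% rep(0, 4)
  p0 <- c(init$u %||% 0, init$v %||% 0, aff)
  r <- cpp_icgn(ref_image, cur_image, center[1], center[2], as.integer(half),
                p0, tol, as.integer(max_iter))
  list(u = r[1], v = r[2], affine = r[3:6], zncc = r[7],
       converged = r[8] == 1, iterations = r[9], code = r[10])
}

# internal: track all grid points between two frames, with neighbour
# re-seeding for failures.  centers/init are matrices over the grid points.
track_points <- function(prev_frame, next_frame, centers, half, step,
                         init_u, init_v, search_range = 10) {
  res <- cpp_track_points(prev_frame, next_frame,
                          centers[, 1], centers[, 2], as.integer(half),
                          init_u, init_v, as.integer(search_range))
  conv <- res[, 8] == 1
  if (any(!conv) && any(conv)) {
    # re-seed failures from the median of converged neighbours within
    # 3 grid steps, then retry once
    for (k in which(!conv)) {
      d2 <- (centers[, 1] - centers[k, 1])^2 + (centers[, 2] - centers[k, 2])^2
      nb <- conv & d2 <= (3 * step)^2 & d2 > 0
      if (!any(nb)) next
      r2 <- cpp_track_points(prev_frame, next_frame,
                             centers[k, 1], centers[k, 2], as.integer(half),
                             median(res[nb, 1]), median(res[nb, 2]),
                             as.integer(search_range))
      if (r2[1, 8] == 1) { res[k, ] <- r2[1, ]; conv[k] <- TRUE }
    }
  }
  res
}

#' Track the grid across one frame pair
#'
#' Correlates every grid subset between two consecutive frames.  Each point
#' is seeded from its own previous solution; points that fail to converge
#' are re-seeded from the median of converged neighbours within three grid
#' steps and retried.
#'
#' @param prev_frame,next_frame numeric matrices.
#' @param grid a [subset_grid()].
#' @param init_field optional `n x 2` matrix of initial `(u, v)` guesses
#'   (zeros when missing).
#' @param search_range half-width of the integer ZNCC fallback search, px.
#' @return data.frame: `point_id, x_ref, y_ref, u, v, zncc, valid,
#'   iterations, code`.
#' @export
track_frame_pair <- function(prev_frame, next_frame, grid, init_field = NULL,
                             search_range = 10) {
  n <- nrow(grid$centers)
  if (is.null(init_field)) init_field <- matrix(0, n, 2)
  res <- track_points(prev_frame, next_frame, grid$centers, grid$half,
                      grid$step, init_field[, 1], init_field[, 2],
                      search_range)
  valid <- res[, 8] == 1
  if (mean(valid) < 0.5)
    stopf("tracking-collapse: %d of %d subsets failed between this frame pair",
          sum(!valid), n)
  data.frame(point_id = seq_len(n),
             x_ref = grid$centers[, 1], y_ref = grid$centers[, 2],
             u = ifelse(valid, res[, 1], NA_real_),
             v = ifelse(valid, res[, 2], NA_real_),
             zncc = ifelse(valid, res[, 7], NA_real_),
             valid = valid,
             iterations = res[, 9], code = res[, 10])
}

#' Track a whole image sequence
#'
#' Accumulates subset displacements over an image sequence.  In
#' `incremental` mode (the sum-of-differentials routine) consecutive frame
#' pairs are correlated directly, with the tracked subset centres moving
#' with the material points, and increments are summed; errors therefore
#' accumulate along the chain.  In `to_reference` mode every frame is
#' correlated against frame 1, seeded by the incremental estimate, which
#' avoids drift accumulation.  Both report per-point cumulative quality as
#' the minimum ZNCC along the chain.
#'
#' @param frames an [image_sequence()] or plain list of matrices.
#' @param grid a [subset_grid()].
#' @param mode `"incremental"` or `"to_reference"`.
#' @param mm_per_px optional physical pixel size for mm output.
#' @param frame_rate frames per second (taken from the sequence when
#'   available).
#' @param search_range integer-search fallback half-width, px.
#' @return An object of class `displacement_field`: matrices `u`, `v`
#'   (`n_frames x n_points`, px, NA where invalid), `zncc` (running
#'   minimum), `valid`, plus the grid and acquisition metadata.
#' @export
accumulate_sequence <- function(frames, grid,
                                mode = c("incremental", "to_reference"),
                                mm_per_px = NULL, frame_rate = NULL,
                                search_range = 10) {
  mode <- match.arg(mode)
  if (inherits(frames, "image_sequence")) {
    frame_rate <- frame_rate %||% frames$frame_rate
    frames <- frames$frames
  }
  nf <- length(frames)
  if (nf < 2) stopf("invalid-parameter: need >= 2 frames")
  np <- nrow(grid$centers)

  u <- matrix(0, nf, np); v <- matrix(0, nf, np)
  q <- matrix(1, nf, np); valid <- matrix(TRUE, nf, np)

  cum_u <- numeric(np); cum_v <- numeric(np)
  inc_u <- numeric(np); inc_v <- numeric(np)
  alive <- rep(TRUE, np)
  minq <- rep(1, np)
  for (k in 2:nf) {
    centers_k <- cbind(grid$centers[, 1] + cum_u, grid$centers[, 2] + cum_v)
    idx <- which(alive)
    if (length(idx) == 0)
      stopf("tracking-collapse: no live points before frame %d", k)
    res <- track_points(frames[[k - 1]], frames[[k]],
                        centers_k[idx, , drop = FALSE], grid$half, grid$step,
                        inc_u[idx], inc_v[idx], search_range)
    conv <- res[, 8] == 1
    if (mean(conv) < 0.5)
      stopf("tracking-collapse: frame pair %d-%d lost %d of %d points",
            k - 1, k, sum(!conv), length(idx))
    alive[idx[!conv]] <- FALSE
    ok <- idx[conv]
    cum_u[ok] <- cum_u[ok] + res[conv, 1]
    cum_v[ok] <- cum_v[ok] + res[conv, 2]
    inc_u[ok] <- res[conv, 1]; inc_v[ok] <- res[conv, 2]
    minq[ok] <- pmin(minq[ok], res[conv, 7])
    u[k, ] <- ifelse(alive, cum_u, NA_real_)
    v[k, ] <- ifelse(alive, cum_v, NA_real_)
    q[k, ] <- ifelse(alive, minq, NA_real_)
    valid[k, ] <- alive
  }

  if (mode == "to_reference") {
    for (k in 2:nf) {
      idx <- which(valid[k, ])
      res <- track_points(frames[[1]], frames[[k]],
                          grid$centers[idx, , drop = FALSE], grid$half,
                          grid$step, u[k, idx], v[k, idx], search_range)
      conv <- res[, 8] == 1
      u[k, idx] <- ifelse(conv, res[, 1], NA_real_)
      v[k, idx] <- ifelse(conv, res[, 2], NA_real_)
      q[k, idx] <- ifelse(conv, pmin(q[k, idx], res[, 7]), NA_real_)
      valid[k, idx] <- conv
    }
  }

  structure(list(u = u, v = v, zncc = q, valid = valid,
                 grid = grid, mode = mode, reference_frame = 1L,
                 mm_per_px = mm_per_px, frame_rate = frame_rate,
                 time = if (!is.null(frame_rate)) (seq_len(nf) - 1) / frame_rate),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "Displacement field (%s): %d frames x %d points, %.1f%% valid%s\n",
    x$mode, nrow(x$u), ncol(x$u), 100 * mean(x$valid),
    if (!is.null(x$uz_mm)) ", 3D (mm)" else ""))
  invisible(x)
}

#' Filter a displacement field by correlation quality
#'
#' Marks points whose cumulative quality (minimum ZNCC along the chain)
#' drops below `zncc_min` at any frame as invalid throughout; the count of
#' removed points is reported as a message.
#'
#' @param field a `displacement_field`.
#' @param zncc_min threshold in `(0, 1]`; non-positive values are clamped
#'   to a small epsilon (degenerate, keeps everything).
#' @return the filtered `displacement_field`.
#' @export
quality_filter <- function(field, zncc_min) {
  if (zncc_min > 1) stopf("invalid-parameter: zncc_min must be <= 1")
  zncc_min <- max(zncc_min, 1e-12)
  drop <- apply(field$zncc < zncc_min & field$valid, 2, any, na.rm = TRUE)
  if (all(drop | !field$valid[nrow(field$valid), ]))
    stopf("empty-field: quality filter at zncc_min = %g removed every point",
          zncc_min)
  if (any(drop))
    message(sprintf("quality_filter: removed %d of %d points below zncc %g",
                    sum(drop), length(drop), zncc_min))
  field$valid[, drop] <- FALSE
  field$u[, drop] <- NA_real_
  field$v[, drop] <- NA_real_
  field
}

#' Export a displacement field as a flat table
#'
#' @param x a `displacement_field`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame: `frame, point_id, x_ref_px, y_ref_px, u_px, v_px,
#'   u_mm, v_mm, zncc, valid` (mm columns NA without a scale).
#' @export
as.data.frame.displacement_field <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  nf <- nrow(x$u); np <- ncol(x$u)
  s <- x$mm_per_px
  data.frame(frame = rep(seq_len(nf), np),
             point_id = rep(seq_len(np), each = nf),
             x_ref_px = rep(x$grid$centers[, 1], each = nf),
             y_ref_px = rep(x$grid$centers[, 2], each = nf),
             u_px = as.vector(x$u), v_px = as.vector(x$v),
             u_mm = if (!is.null(s)) as.vector(x$u) * s else NA_real_,
             v_mm = if (!is.null(s)) as.vector(x$v) * s else NA_real_,
             zncc = as.vector(x$zncc),
             valid = as.vector(x$valid))
}
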