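#' Scalar time-series trace
#'
#' Uniformly sampled scalar series with per-sample dispersion, the common
#' currency of the cardiac descriptors (displacement components, tissue
#' velocity, fractional shortening, strain, strain rate).
#'
#' @param values numeric series (NA marks flagged gaps).
#' @param time sample times, s (uniform).
#' @param sd per-sample dispersion in the same units (optional).
#' @param label short name.
#' @param units unit string (`"mm"`, `"cm/s"`, `"%"`, `"1/s"`).
#' @return object of class `dic_trace`.
#' @export
dic_trace <- function(values, time, sd = NULL, label = "", units = "") {
  n <- length(values)
  if (length(time) != n)
    stopf("invalid-parameter: trace values/time lengths differ")
  if (n > 2) {
    dt <- diff(time)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9)
      stopf("invalid-parameter: trace sampling must be uniform")
  }
  if (is.null(sd)) sd <- rep(NA_real_, n)
  structure(list(values = as.numeric(values), time = as.numeric(time),
                 sd = as.numeric(sd), label = label, units = units),
            class = "dic_trace")
}

#' @export
print.dic_trace <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("Trace '%s' (%s): %d samples over %.3g s, range [%.4g, %.4g]\n",
              x$label, x$units, length(x$values),
              diff(range(x$time)), rng[1], rng[2]))
  invisible(x)
}

#' @export
length.dic_trace <- function(x) length(x$values)

trace_rate <- function(tr) 1 / diff(tr$time[1:2])

#' Rectangular region of interest
#'
#' @param x0,y0 top-left corner, reference-image px.
#' @param width,height extent, px.
#' @return object of class `roi_def`.
#' @export
roi_def <- function(x0, y0, width, height) {
  check_scalar(width, "width", lower = 1)
  check_scalar(height, "height", lower = 1)
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "roi_def")
}

#' Virtual extensometer definition
#'
#' A line between two material points in the reference image; its tracked
#' length measures Lagrangian strain along that direction.
#'
#' @param p1,p2 endpoints `c(x, y)` in reference-image px (distinct).
#' @return object of class `extensometer_def`.
#' @export
extensometer_def <- function(p1, p2) {
  if (isTRUE(all.equal(p1, p2)))
    stopf("invalid-parameter: extensometer endpoints must be distinct")
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2)),
            class = "extensometer_def")
}

# mm-resolved displacement components of a field: 3D (triangulated) when
# present, 2D scaled by mm_per_px otherwise
field_mm <- function(field) {
  if (!is.null(field$ux_mm))
    return(list(ux = field$ux_mm, uy = field$uy_mm, uz = field$uz_mm))
  if (is.null(field$mm_per_px))
    stopf("invalid-parameter: field has no mm scale (mm_per_px or 3D lift)")
  list(ux = field$u * field$mm_per_px, uy = field$v * field$mm_per_px,
       uz = NULL)
}

roi_point_mask <- function(grid, roi) {
  m <- grid$centers[, 1] >= roi$x0 &
    grid$centers[, 1] < roi$x0 + roi$width &
    grid$centers[, 2] >= roi$y0 &
    grid$centers[, 2] < roi$y0 + roi$height
  if (sum(m) < 4)
    stopf("invalid-parameter: ROI contains %d grid points (need >= 4)", sum(m))
  m
}

#' ROI-averaged displacement traces
#'
#' Per frame, the mean and standard deviation over the valid ROI grid
#' points of each displacement component and of the per-point vector
#' length `|u|` (computed per point, then averaged -- not the length of
#' the mean vector).  A frame where fewer than 25% of ROI points are valid
#' is flagged missing (NA).
#'
#' @param field a `displacement_field` (2D with an mm scale, or 3D-lifted).
#' @param roi a [roi_def()].
#' @return named list of [dic_trace()]s: `V_x`, `V_y`, `V_z` (3D fields
#'   only), `V_l`, all in mm.
#' @export
roi_traces <- function(field, roi) {
  comp <- field_mm(field)
  sel <- roi_point_mask(field$grid, roi)
  nf <- nrow(field$u)
  tm <- field$time %||% (seq_len(nf) - 1)
  valid <- field$valid[, sel, drop = FALSE]
  frac <- rowMeans(valid)
  stat <- function(M) {
    M <- M[, sel, drop = FALSE]
    M[!valid] <- NA
    mu <- rowMeans(M, na.rm = TRUE)
    sdv <- apply(M, 1, sd, na.rm = TRUE)
    mu[frac < 0.25] <- NA; sdv[frac < 0.25] <- NA
    list(mean = mu, sd = sdv)
  }
  vl_mat <- sqrt(comp$ux^2 + comp$uy^2 +
                   if (!is.null(comp$uz)) comp$uz^2 else 0)
  out <- list(
    V_x = { s <- stat(comp$ux); dic_trace(s$mean, tm, s$sd, "V_x", "mm") },
    V_y = { s <- stat(comp$uy); dic_trace(s$mean, tm, s$sd, "V_y", "mm") })
  if (!is.null(comp$uz))
    out$V_z <- { s <- stat(comp$uz); dic_trace(s$mean, tm, s$sd, "V_z", "mm") }
  out$V_l <- { s <- stat(vl_mat); dic_trace(s$mean, tm, s$sd, "V_l", "mm") }
  out
}

# local minima of v with topographic prominence >= prom (absolute units)
find_prominent_minima <- function(v, prom) {
  n <- length(v)
  idx <- which(diff(sign(diff(v))) > 0) + 1  # strict local minima
  keep <- logical(length(idx))
  prominences <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]; h <- v[i]
    # walk outwards until a sample lower than v[i]; barrier = max en route
    l <- i - 1; barl <- -Inf
    while (l >= 1 && v[l] >= h) { barl <- max(barl, v[l]); l <- l - 1 }
    if (l < 1) barl <- max(barl, -Inf)
    r <- i + 1; barr <- -Inf
    while (r <= n && v[r] >= h) { barr <- max(barr, v[r]); r <- r + 1 }
    p <- min(if (is.finite(barl)) barl else Inf,
             if (is.finite(barr)) barr else Inf) - h
    if (!is.finite(p)) p <- max(v, na.rm = TRUE) - h
    prominences[j] <- p
    keep[j] <- p >= prom
  }
  list(idx = idx[keep], prominence = prominences[keep],
       all_idx = idx, all_prominence = prominences)
}

#' Segment a vector-length trace into heartbeats
#'
#' Beats are delimited at local minima of `V_l` whose topographic
#' prominence is at least `prominence_frac` of the global range and which
#' are separated by at least `min_beat_s`.  The trace start (end) counts as
#' a boundary when its value is itself near the resting minimum, so a
#' sequence beginning at end-diastole contributes its first beat.  Leading
#' or trailing partial beats are excluded.
#'
#' @param v_l a [dic_trace()] of vector length, mm.
#' @param min_beat_s minimum beat duration, s.
#' @param prominence_frac prominence threshold as a fraction of the global
#'   max - min.
#' @return object of class `beat_segmentation`: `intervals` (matrix of
#'   half-open `[start, end)` frame indices, one row per complete beat),
#'   `boundaries`, and detection diagnostics.
#' @export
segment_beats <- function(v_l, min_beat_s = 0.4, prominence_frac = 0.3) {
  v <- v_l$values
  n <- length(v)
  if (any(is.na(v))) v <- approx_na(v)
  rng <- max(v) - min(v)
  if (rng <= .Machine$double.eps * max(abs(v), 1))
    stopf("segmentation-failure: trace is constant")
  fm <- find_prominent_minima(v, prominence_frac * rng)
  bnd <- fm$idx
  # endpoint boundaries: the trace resting at its minimum level
  near_min <- function(x) (x - min(v)) <= 0.1 * rng
  if (near_min(v[1])) bnd <- c(1L, bnd)
  if (near_min(v[n])) bnd <- c(bnd, as.integer(n))
  bnd <- sort(unique(bnd))
  # enforce minimum separation, keeping the deeper minimum
  rate <- trace_rate(v_l)
  min_gap <- max(1, round(min_beat_s * rate))
  i <- 2
  while (i <= length(bnd)) {
    if (bnd[i] - bnd[i - 1] < min_gap) {
      drop <- if (v[bnd[i]] < v[bnd[i - 1]]) i - 1 else i
      bnd <- bnd[-drop]
    } else i <- i + 1
  }
  if (length(bnd) < 2)
    stopf(paste0("segmentation-failure: no two qualifying minima ",
                 "(candidates %d, max prominence %.3g of range %.3g)"),
          length(fm$all_idx),
          if (length(fm$all_prominence)) max(fm$all_prominence) else 0, rng)
  intervals <- cbind(start = bnd[-length(bnd)], end = bnd[-1])
  structure(list(intervals = intervals, boundaries = bnd,
                 prominences = fm$prominence,
                 candidates = fm$all_idx,
                 candidate_prominences = fm$all_prominence),
            class = "beat_segmentation")
}

approx_na <- function(v) {
  if (!any(is.na(v))) return(v)
  ok <- which(!is.na(v))
  stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat(sprintf("Beat segmentation: %d complete beats (boundaries at frames %s)\n",
              nrow(x$intervals), paste(x$boundaries, collapse = ", ")))
  invisible(x)
}

# segments covering the whole trace: partial head/tail plus complete beats
full_segments <- function(beats, n) {
  b <- beats$boundaries
  segs <- beats$intervals
  if (b[1] > 1) segs <- rbind(c(1, b[1]), segs)
  if (b[length(b)] < n) segs <- rbind(segs, c(b[length(b)], n + 1))
  segs
}

#' Stitch per-beat displacement fields into one continuous field
#'
#' Each per-beat field is referenced to its own first frame; beat `k` is
#' offset by the accumulated end-displacement of the preceding beats so
#' the result is one continuous series referenced to the global first
#' frame.  Consecutive fields must share the grid and be temporally
#' contiguous (each beat's first frame is the previous beat's last frame).
#'
#' @param per_beat_fields list of `displacement_field`s.
#' @return a single stitched `displacement_field`.
#' @export
stitch_beats <- function(per_beat_fields) {
  nb <- length(per_beat_fields)
  if (nb == 0) stopf("invalid-parameter: no beats supplied")
  if (nb == 1) return(per_beat_fields[[1]])
  f1 <- per_beat_fields[[1]]
  np <- ncol(f1$u)
  u <- f1$u; v <- f1$v; q <- f1$zncc; valid <- f1$valid; tm <- f1$time
  off_u <- u[nrow(u), ]; off_v <- v[nrow(v), ]
  for (k in 2:nb) {
    fk <- per_beat_fields[[k]]
    if (ncol(fk$u) != np)
      stopf("stitching-gap: beat %d uses a different grid", k)
    if (is.null(tm) || is.null(fk$time) ||
        abs(fk$time[1] - tm[length(tm)]) > 1e-9)
      stopf("stitching-gap: beat %d does not start where beat %d ends",
            k, k - 1)
    rows <- 2:nrow(fk$u)   # first frame duplicates the previous beat's last
    u <- rbind(u, sweep(fk$u[rows, , drop = FALSE], 2, off_u, `+`))
    v <- rbind(v, sweep(fk$v[rows, , drop = FALSE], 2, off_v, `+`))
    q <- rbind(q, fk$zncc[rows, , drop = FALSE])
    valid <- rbind(valid, fk$valid[rows, , drop = FALSE])
    tm <- c(tm, fk$time[rows])
    off_u <- u[nrow(u), ]; off_v <- v[nrow(v), ]
  }
  out <- f1
  out$u <- u; out$v <- v; out$zncc <- q; out$valid <- valid; out$time <- tm
  out
}

sgolay_smooth <- function(x, window) {
  if (window < 3) return(x)
  as.numeric(signal::sgolayfilt(x, p = 2, n = window))
}

deriv_central <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Tissue velocity from the vector-length trace
#'
#' The rate of change of the displacement-vector length: the trace is
#' smoothed with a local quadratic (Savitzky-Golay) filter, differentiated
#' by central differences (one-sided at the endpoints) and converted from
#' mm/s to cm/s.
#'
#' @param v_l a [dic_trace()] of `V_l`, mm.
#' @param smoothing_window odd window length, samples (must be shorter
#'   than the trace).
#' @return a [dic_trace()] in cm/s.
#' @export
tissue_velocity <- function(v_l, smoothing_window = 5) {
  n <- length(v_l$values)
  if (smoothing_window >= n)
    stopf("invalid-window: smoothing window %d >= trace length %d",
          smoothing_window, n)
  if (smoothing_window %% 2 != 1)
    stopf("invalid-window: smoothing window must be odd")
  x <- sgolay_smooth(approx_na(v_l$values), smoothing_window)
  d <- deriv_central(x, 1 / trace_rate(v_l))
  dic_trace(d / 10, v_l$time, label = "TV", units = "cm/s")
}

local_extrema <- function(v, minima = TRUE) {
  s <- if (minima) diff(sign(diff(v))) > 0 else diff(sign(diff(v))) < 0
  which(s) + 1
}

#' Detect tissue-velocity characteristic points
#'
#' Per complete beat: `TV_s` is the most positive velocity (motion towards
#' the apex), `TV_e` the most negative velocity (early-diastolic
#' recoil), and `TV_a` the most negative *local* minimum strictly after
#' `TV_e` within the beat (the atrial kick).  A missing atrial dip is
#' flagged absent, not imputed; a beat whose velocity never changes sign
#' direction is flagged as a detection failure.
#'
#' @param tv tissue-velocity [dic_trace()], cm/s.
#' @param beats a [segment_beats()] result.
#' @return data.frame, one row per beat: `beat, TVs, TVs_frame, TVe,
#'   TVe_frame, TVa, TVa_frame, flag`.
#' @export
detect_tv_points <- function(tv, beats) {
  v <- tv$values
  out <- do.call(rbind, lapply(seq_len(nrow(beats$intervals)), function(b) {
    s <- beats$intervals[b, 1]; e <- beats$intervals[b, 2] - 1
    if (e - s + 1 < 5)
      return(data.frame(beat = b, TVs = NA, TVs_frame = NA, TVe = NA,
                        TVe_frame = NA, TVa = NA, TVa_frame = NA,
                        flag = "too-short"))
    w <- v[s:e]
    if (all(diff(w) >= 0) || all(diff(w) <= 0))
      return(data.frame(beat = b, TVs = NA, TVs_frame = NA, TVe = NA,
                        TVe_frame = NA, TVa = NA, TVa_frame = NA,
                        flag = "monotone"))
    is_ <- which.max(w); ie <- which.min(w)
    # atrial dip: most negative interior local minimum strictly after TVe;
    # negative by definition (motion away from the apex), and required to
    # exceed 2% of the velocity scale so smoothing ripple on a flat
    # diastasis is not mistaken for an atrial kick
    lm <- local_extrema(w, minima = TRUE)
    lm <- lm[lm > ie & lm < length(w) & w[lm] < -0.02 * max(abs(w))]
    flag <- "ok"
    if (length(lm) == 0) { ia <- NA; flag <- "TVa-absent" }
    else ia <- lm[which.min(w[lm])]
    data.frame(beat = b,
               TVs = w[is_], TVs_frame = s + is_ - 1,
               TVe = w[ie], TVe_frame = s + ie - 1,
               TVa = if (is.na(ia)) NA_real_ else w[ia],
               TVa_frame = if (is.na(ia)) NA_integer_ else s + ia - 1,
               flag = flag)
  }))
  out
}

# lattice gradient of a ny x nx matrix by least-squares plane fit over a
# window x window neighbourhood (separable on the regular grid): central
# differences box-averaged over the window, one-sided at lattice edges
lattice_grad <- function(U, h, window) {
  ny <- nrow(U); nx <- ncol(U)
  gx <- matrix(NA_real_, ny, nx); gy <- gx
  if (nx >= 3) gx[, 2:(nx - 1)] <- (U[, 3:nx] - U[, 1:(nx - 2)]) / (2 * h)
  gx[, 1] <- (U[, 2] - U[, 1]) / h
  gx[, nx] <- (U[, nx] - U[, nx - 1]) / h
  if (ny >= 3) gy[2:(ny - 1), ] <- (U[3:ny, ] - U[1:(ny - 2), ]) / (2 * h)
  gy[1, ] <- (U[2, ] - U[1, ]) / h
  gy[ny, ] <- (U[ny, ] - U[ny - 1, ]) / h
  if (window > 1) {
    gx <- box_mean(gx, window)
    gy <- box_mean(gy, window)
  }
  list(gx = gx, gy = gy)
}

box_mean <- function(M, w) {
  half <- (w - 1) / 2
  ny <- nrow(M); nx <- ncol(M)
  out <- M
  csum <- function(v, n) {
    # running mean with shrinking windows at the edges, NA-aware
    sapply(seq_len(n), function(i) {
      j <- max(1, i - half):min(n, i + half)
      mean(v[j], na.rm = FALSE)
    })
  }
  out <- apply(M, 2, csum, n = ny)
  out <- t(apply(out, 1, csum, n = nx))
  out
}

#' Local surface strain field and ROI summary
#'
#' Per grid point and frame, the in-plane displacement gradient is
#' estimated by a least-squares plane fit over a `window_points` square
#' neighbourhood of the regular lattice; the Green-Lagrange tensor
#' `E = (F'F - I)/2` then yields principal stretches, reported as
#' engineering principal strains `(lambda - 1) * 100%` -- finite-strain
#' correct and invariant to rigid rotation.  The reference state defaults
#' to the sequence start; `reference = "end_systole"` re-references each
#' beat to its most-contracted frame (minimum ROI-mean spacing), the
#' convention of echo-style strain reporting.
#'
#' @param field a `displacement_field` with an mm scale.
#' @param window_points odd window edge length in grid points (>= 3).
#' @param roi optional [roi_def()] for the per-frame summary (defaults to
#'   all points).
#' @param reference `"first"` or `"end_systole"`.
#' @param beats [segment_beats()] result, required for
#'   `reference = "end_systole"`.
#' @return object of class `strain_summary`: data.frame `per_frame`
#'   (`time, e_max, e_min, Exx, Eyy, Exy, e_max_sd, e_min_sd`, strains in
#'   %) plus per-point matrices `point_e_max`, `point_e_min` (%).
#' @export
local_strain_field <- function(field, window_points = 3, roi = NULL,
                               reference = c("first", "end_systole"),
                               beats = NULL) {
  reference <- match.arg(reference)
  if (window_points < 3 || window_points %% 2 != 1)
    stopf("invalid-parameter: window_points must be odd and >= 3")
  if (field$grid$nx < 3 || field$grid$ny < 3)
    stopf("invalid-parameter: strain window needs >= 3x3 grid points")
  comp <- field_mm(field)
  nf <- nrow(field$u); np <- ncol(field$u)
  nx <- field$grid$nx; ny <- field$grid$ny
  h <- field$grid$step * (field$mm_per_px %||% 1)
  tm <- field$time %||% (seq_len(nf) - 1)

  Fc <- array(NA_real_, c(nf, np, 4))   # F11 F12 F21 F22
  for (k in seq_len(nf)) {
    Ux <- matrix(comp$ux[k, ], ny, nx, byrow = TRUE)
    Uy <- matrix(comp$uy[k, ], ny, nx, byrow = TRUE)
    gx <- lattice_grad(Ux, h, window_points)
    gy <- lattice_grad(Uy, h, window_points)
    Fc[k, , 1] <- as.vector(t(1 + gx$gx))
    Fc[k, , 2] <- as.vector(t(gx$gy))
    Fc[k, , 3] <- as.vector(t(gy$gx))
    Fc[k, , 4] <- as.vector(t(1 + gy$gy))
  }

  if (reference == "end_systole") {
    if (is.null(beats))
      stopf("invalid-parameter: end_systole reference requires `beats`")
    vl <- sqrt(comp$ux^2 + comp$uy^2)
    mean_vl <- rowMeans(vl, na.rm = TRUE)
    segs <- full_segments(beats, nf)
    Fr <- Fc
    for (si in seq_len(nrow(segs))) {
      idx <- segs[si, 1]:(segs[si, 2] - 1)
      es <- idx[which.max(mean_vl[idx])]
      # F_rel = F_t F_es^-1, per point, closed form 2x2
      a <- Fc[es, , 1]; b <- Fc[es, , 2]; cc <- Fc[es, , 3]; d <- Fc[es, , 4]
      det <- a * d - b * cc
      i11 <- d / det; i12 <- -b / det; i21 <- -cc / det; i22 <- a / det
      for (k in idx) {
        f11 <- Fc[k, , 1]; f12 <- Fc[k, , 2]
        f21 <- Fc[k, , 3]; f22 <- Fc[k, , 4]
        Fr[k, , 1] <- f11 * i11 + f12 * i21
        Fr[k, , 2] <- f11 * i12 + f12 * i22
        Fr[k, , 3] <- f21 * i11 + f22 * i21
        Fr[k, , 4] <- f21 * i12 + f22 * i22
      }
    }
    Fc <- Fr
  }

  F11 <- Fc[, , 1]; F12 <- Fc[, , 2]; F21 <- Fc[, , 3]; F22 <- Fc[, , 4]
  Exx <- (F11^2 + F21^2 - 1) / 2
  Eyy <- (F12^2 + F22^2 - 1) / 2
  Exy <- (F11 * F12 + F21 * F22) / 2
  mid <- (Exx + Eyy) / 2
  rad <- sqrt(((Exx - Eyy) / 2)^2 + Exy^2)
  e1 <- mid + rad; e2 <- mid - rad
  l1 <- sqrt(pmax(1 + 2 * e1, 0)); l2 <- sqrt(pmax(1 + 2 * e2, 0))
  p_max <- (l1 - 1) * 100; p_min <- (l2 - 1) * 100
  p_max[!field$valid] <- NA; p_min[!field$valid] <- NA

  sel <- if (is.null(roi)) rep(TRUE, np) else roi_point_mask(field$grid, roi)
  rmean <- function(M) rowMeans(M[, sel, drop = FALSE], na.rm = TRUE)
  rsd <- function(M) apply(M[, sel, drop = FALSE], 1, sd, na.rm = TRUE)
  per_frame <- data.frame(time = tm,
                          e_max = rmean(p_max), e_min = rmean(p_min),
                          Exx = rmean(Exx), Eyy = rmean(Eyy),
                          Exy = rmean(Exy),
                          e_max_sd = rsd(p_max), e_min_sd = rsd(p_min))
  structure(list(per_frame = per_frame,
                 point_e_max = p_max, point_e_min = p_min,
                 reference = reference, window_points = window_points),
            class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf(
    "Strain summary (%s reference): %d frames; e_max peak %.3g%%, e_min trough %.3g%%\n",
    x$reference, nrow(x$per_frame),
    max(x$per_frame$e_max, na.rm = TRUE), min(x$per_frame$e_min, na.rm = TRUE)))
  invisible(x)
}

# inverse-distance-weighted interpolation of per-frame displacement at one
# reference-image point; k nearest valid grid neighbours, weights 1/d^2
idw_displacement <- function(field, comp, pt, k = 6) {
  d2 <- (field$grid$centers[, 1] - pt[1])^2 +
    (field$grid$centers[, 2] - pt[2])^2
  ord <- order(d2)[seq_len(min(k, length(d2)))]
  nf <- nrow(field$u)
  has_z <- !is.null(comp$uz)
  out <- matrix(NA_real_, nf, 3)
  w_all <- 1 / pmax(d2[ord], 1e-12)
  for (fr in seq_len(nf)) {
    ok <- field$valid[fr, ord]
    if (sum(ok) < 3) next  # gap flagged
    w <- w_all[ok]
    idx <- ord[ok]
    out[fr, 1] <- sum(w * comp$ux[fr, idx]) / sum(w)
    out[fr, 2] <- sum(w * comp$uy[fr, idx]) / sum(w)
    out[fr, 3] <- if (has_z) sum(w * comp$uz[fr, idx]) / sum(w) else 0
  }
  out
}

#' Virtual-extensometer length trace
#'
#' Endpoint displacements are interpolated from the grid field
#' (inverse-distance weighting over the nearest valid grid points, at
#' least three per endpoint); `L(t)` is the Euclidean distance between the
#' displaced endpoints in mm (3D when the field has been lifted).
#'
#' @param field a `displacement_field` with an mm scale.
#' @param ext an [extensometer_def()].
#' @return a [dic_trace()] of length, mm; frames where an endpoint cannot
#'   be interpolated are flagged NA.
#' @export
extensometer_length <- function(field, ext) {
  comp <- field_mm(field)
  s <- field$mm_per_px %||%
    stopf("invalid-parameter: extensometer needs mm_per_px")
  in_hull <- function(p) {
    p[1] >= min(field$grid$centers[, 1]) - field$grid$step &&
      p[1] <= max(field$grid$centers[, 1]) + field$grid$step &&
      p[2] >= min(field$grid$centers[, 2]) - field$grid$step &&
      p[2] <= max(field$grid$centers[, 2]) + field$grid$step
  }
  if (!in_hull(ext$p1) || !in_hull(ext$p2))
    stopf("invalid-parameter: extensometer endpoint outside the tracked grid")
  u1 <- idw_displacement(field, comp, ext$p1)
  u2 <- idw_displacement(field, comp, ext$p2)
  base <- c((ext$p2[1] - ext$p1[1]) * s, (ext$p2[2] - ext$p1[2]) * s, 0)
  d <- sweep(u2 - u1, 2, base, `+`)
  L <- sqrt(rowSums(d^2))
  nf <- nrow(field$u)
  dic_trace(L, field$time %||% (seq_len(nf) - 1), label = "L", units = "mm")
}

#' Fractional shortening from the extensometer length (per-beat normalised)
#'
#' `FS(t) = (1 - L(t) / L_max) * 100` with `L_max` the maximum extensometer
#' length within the beat (the maximum-dilation, end-diastolic state of
#' that beat).  FS is therefore in `[0, 100)` and reaches 0 within every
#' beat.  Leading/trailing partial segments are normalised by their own
#' maximum.
#'
#' @param l extensometer length [dic_trace()], mm.
#' @param beats a [segment_beats()] result.
#' @return a [dic_trace()] of FS, %.
#' @export
fractional_shortening <- function(l, beats) {
  L <- l$values
  n <- length(L)
  fs <- rep(NA_real_, n)
  segs <- full_segments(beats, n)
  for (si in seq_len(nrow(segs))) {
    idx <- segs[si, 1]:(segs[si, 2] - 1)
    lmax <- max(L[idx], na.rm = TRUE)
    if (!is.finite(lmax) || lmax <= 0)
      stopf("invalid-length: non-positive per-beat maximum length")
    fs[idx] <- (1 - L[idx] / lmax) * 100
  }
  dic_trace(fs, l$time, label = "FS", units = "%")
}

#' Conventional fractional shortening from cavity dimensions
#'
#' `FS = (LVEDD - LVESD) / LVEDD * 100`, the echocardiographic M-mode
#' definition from end-diastolic and end-systolic dimensions.
#'
#' @param lvedd end-diastolic dimension, mm (> 0).
#' @param lvesd end-systolic dimension, mm (`0 <= lvesd <= lvedd`).
#' @return FS in %.
#' @export
fs_conventional <- function(lvedd, lvesd) {
  if (!is_scalar_num(lvedd) || lvedd <= 0)
    stopf("invalid-dimension: LVEDD must be > 0")
  if (!is_scalar_num(lvesd) || lvesd < 0 || lvesd > lvedd)
    stopf("invalid-dimension: LVESD must satisfy 0 <= LVESD <= LVEDD")
  (lvedd - lvesd) / lvedd * 100
}

#' Extensometer strain, strain rate and their characteristic points
#'
#' Engineering strain `(L(t) - L_ref) / L_ref * 100` with `L_ref` the
#' per-beat maximum length (so strain is 0 at end-diastole and negative in
#' systole); strain rate is the smoothed time derivative of strain/100
#' (1/s).  Per complete beat: `SR_s` the negative extremum (systolic),
#' `SR_e` the first positive local maximum (early diastolic), `SR_a` the
#' second positive local maximum (atrial), and `S_s` the peak-to-peak
#' strain (max - min within the beat).
#'
#' @param l extensometer length [dic_trace()], mm.
#' @param beats a [segment_beats()] result.
#' @param smoothing_window odd Savitzky-Golay window, samples.
#' @return list: `strain` ([dic_trace()], %), `strain_rate`
#'   ([dic_trace()], 1/s), `points` (data.frame per beat: `beat, SRs,
#'   SRs_frame, SRe, SRe_frame, SRa, SRa_frame, Ss, flag`).
#' @export
strain_and_rate <- function(l, beats, smoothing_window = 5) {
  n <- length(l$values)
  if (smoothing_window >= n)
    stopf("invalid-window: smoothing window %d >= trace length %d",
          smoothing_window, n)
  L <- l$values
  strain <- rep(NA_real_, n)
  segs <- full_segments(beats, n)
  for (si in seq_len(nrow(segs))) {
    idx <- segs[si, 1]:(segs[si, 2] - 1)
    lref <- max(L[idx], na.rm = TRUE)
    if (!is.finite(lref) || lref <= 0)
      stopf("invalid-length: non-positive per-beat reference length")
    strain[idx] <- (L[idx] - lref) / lref * 100
  }
  sm <- sgolay_smooth(approx_na(strain), smoothing_window)
  rate <- deriv_central(sm / 100, 1 / trace_rate(l))
  pts <- do.call(rbind, lapply(seq_len(nrow(beats$intervals)), function(b) {
    s <- beats$intervals[b, 1]; e <- beats$intervals[b, 2] - 1
    w <- rate[s:e]; st <- strain[s:e]
    ss <- max(st, na.rm = TRUE) - min(st, na.rm = TRUE)
    if (length(w) < 5 || all(diff(w) >= 0) || all(diff(w) <= 0))
      return(data.frame(beat = b, SRs = NA, SRs_frame = NA, SRe = NA,
                        SRe_frame = NA, SRa = NA, SRa_frame = NA,
                        Ss = ss, flag = "detection-failure"))
    is_ <- which.min(w)
    # diastolic peaks must rise above 2% of the rate scale (ripple guard)
    lm <- local_extrema(w, minima = FALSE)
    lm <- lm[w[lm] > 0.02 * max(abs(w))]
    flag <- "ok"
    if (length(lm) == 0) {
      ie <- NA; ia <- NA; flag <- "SRe-absent"
    } else {
      ie <- lm[1]
      ia <- if (length(lm) >= 2) lm[2] else NA
      if (is.na(ia)) flag <- "SRa-absent"
    }
    data.frame(beat = b,
               SRs = w[is_], SRs_frame = s + is_ - 1,
               SRe = if (is.na(ie)) NA_real_ else w[ie],
               SRe_frame = if (is.na(ie)) NA_integer_ else s + ie - 1,
               SRa = if (is.na(ia)) NA_real_ else w[ia],
               SRa_frame = if (is.na(ia)) NA_integer_ else s + ia - 1,
               Ss = ss, flag = flag)
  }))
  list(strain = dic_trace(strain, l$time, label = "strain", units = "%"),
       strain_rate = dic_trace(rate, l$time, label = "strain rate",
                               units = "1/s"),
       points = pts)
}

#' Longitudinal and horizontal directional strains
#'
#' Engineering strain (relative to the reference-frame length) along the
#' extensometer direction and along the in-plane perpendicular through its
#' midpoint, the latter realised as a second virtual extensometer of equal
#' initial length.  If the perpendicular line would exit the tracked grid
#' it is shortened symmetrically with a warning.
#'
#' @param field a `displacement_field` with an mm scale.
#' @param ext an [extensometer_def()].
#' @return list of two [dic_trace()]s (%): `longitudinal`, `horizontal`,
#'   each carrying its extensometer as attribute `"extensometer"`.
#' @export
directional_strains <- function(field, ext) {
  p1 <- ext$p1; p2 <- ext$p2
  mid <- (p1 + p2) / 2
  dvec <- (p2 - p1) / 2
  perp <- c(-dvec[2], dvec[1])
  lo <- c(min(field$grid$centers[, 1]), min(field$grid$centers[, 2])) -
    field$grid$step
  hi <- c(max(field$grid$centers[, 1]), max(field$grid$centers[, 2])) +
    field$grid$step
  shrink <- 1
  inside <- function(s) all(mid + s * perp >= lo & mid + s * perp <= hi &
                              mid - s * perp >= lo & mid - s * perp <= hi)
  while (!inside(shrink) && shrink > 0.05) shrink <- shrink * 0.9
  if (shrink < 1)
    warnf("horizontal extensometer shortened to %.0f%% of the longitudinal length to stay on the grid",
          100 * shrink)
  hext <- extensometer_def(mid - shrink * perp, mid + shrink * perp)
  eng <- function(e) {
    L <- extensometer_length(field, e)
    dic_trace((L$values / L$values[1] - 1) * 100, L$time,
              label = "strain", units = "%")
  }
  long_tr <- eng(ext)
  horiz_tr <- eng(hext)
  long_tr$label <- "longitudinal strain"
  horiz_tr$label <- "horizontal strain"
  attr(long_tr, "extensometer") <- ext
  attr(horiz_tr, "extensometer") <- hext
  list(longitudinal = long_tr, horizontal = horiz_tr)
}
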