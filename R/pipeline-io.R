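#' Read a grayscale image sequence
#'
#' Accepts a multi-page TIFF file or a `sprintf`-style pattern of numbered
#' frames (e.g. `"frame_%04d.tif"`); frames are loaded in index order,
#' RGB input is converted to luminance (Rec. 709) with a warning, and
#' timestamps are synthesized from the frame rate.
#'
#' @param path_or_pattern path to a multi-page TIFF, or a pattern
#'   containing a `%d` directive for numbered frames.
#' @param frame_rate acquisition rate, Hz.
#' @param camera_id label stored on the sequence.
#' @return an [image_sequence()]; intensities on the native `[0, 2^bits-1]`
#'   scale.
#' @export
read_image_sequence <- function(path_or_pattern, frame_rate,
                                camera_id = "cam1") {
  to_gray <- function(a) {
    if (length(dim(a)) == 3) {
      warnf("RGB input converted to luminance")
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    }
    a
  }
  if (grepl("%0?[0-9]*d", path_or_pattern)) {
    dir <- dirname(path_or_pattern)
    rx <- paste0("^", gsub("%0?[0-9]*d", "([0-9]+)",
                           gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                basename(path_or_pattern))), "$")
    files <- list.files(dir, full.names = FALSE)
    hits <- regmatches(files, regexec(rx, files))
    idx <- vapply(hits, function(h) if (length(h) == 2) as.integer(h[2]) else NA_integer_,
                  integer(1))
    files <- files[!is.na(idx)]; idx <- idx[!is.na(idx)]
    if (length(files) == 0)
      stopf("format error: no frames match pattern '%s'", path_or_pattern)
    o <- order(idx); files <- files[o]; idx <- idx[o]
    gaps <- setdiff(seq(min(idx), max(idx)), idx)
    if (length(gaps) > 0)
      stopf("gap error: frame %d missing from the numbered set", gaps[1])
    frames <- lapply(file.path(dir, files), function(f)
      to_gray(tiff::readTIFF(f)))
  } else {
    pages <- tiff::readTIFF(path_or_pattern, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray)
  }
  bits <- attr(frames[[1]], "bits.per.sample") %||% 8
  frames <- lapply(frames, function(f) {
    attributes(f)[setdiff(names(attributes(f)), "dim")] <- NULL
    f * (2^bits - 1)
  })
  image_sequence(frames, frame_rate, bit_depth = bits, camera_id = camera_id)
}

#' Write an image sequence as a multi-page TIFF
#'
#' @param seq an [image_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_sequence <- function(seq, path) {
  imax <- 2^seq$bit_depth - 1
  pages <- lapply(seq$frames, function(f) pmin(pmax(f / imax, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = seq$bit_depth)
  invisible(path)
}

#' Write / read a displacement field as CSV
#'
#' Stable column contract (version 1): `frame, point_id, x_ref_px,
#' y_ref_px, u_px, v_px, u_mm, v_mm, zncc, valid`.
#'
#' @param field a `displacement_field`.
#' @param path CSV path.
#' @return `path` invisibly ([write_field_csv()]); a data.frame
#'   ([read_field_csv()]).
#' @export
write_field_csv <- function(field, path) {
  write.csv(format(as.data.frame(field), digits = 17, trim = TRUE,
                   scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a trace (or list of traces) as CSV
#'
#' Columns: `time_s, value, std, label, units`.
#'
#' @param traces a [dic_trace()] or named list of them.
#' @param path CSV path.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "dic_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = tr$time, value = tr$values, std = tr$sd,
               label = tr$label, units = tr$units)))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground truth as CSV
#'
#' Columns: `frame, point_id, X_mm, Y_mm, Z_mm, ux_mm, uy_mm, uz_mm, Exx,
#' Eyy, Exy, L_mm`.
#'
#' @param gt a `ground_truth` object from [generate_stereo_sequences()].
#' @param path CSV path.
#' @export
write_ground_truth_csv <- function(gt, path) {
  nf <- length(gt$time); np <- nrow(gt$grid_mm)
  df <- data.frame(frame = rep(seq_len(nf), each = np),
                   point_id = rep(seq_len(np), nf),
                   X_mm = rep(gt$grid_mm[, 1], nf),
                   Y_mm = rep(gt$grid_mm[, 2], nf),
                   Z_mm = 0,
                   ux_mm = as.vector(t(gt$u[, , 1])),
                   uy_mm = as.vector(t(gt$u[, , 2])),
                   uz_mm = as.vector(t(gt$u[, , 3])),
                   Exx = rep(gt$strain$Exx, each = np),
                   Eyy = rep(gt$strain$Eyy, each = np),
                   Exy = rep(gt$strain$Exy, each = np),
                   L_mm = rep(gt$L_mm, each = np))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a camera model as JSON
#'
#' The 3x4 projection matrix is stored row-major under `projection_row_major`
#' with an explicit convention note (world mm to image px, 1-based pixel
#' centres, x rightward / y downward).
#'
#' @param camera a [camera_model()].
#' @param path JSON path.
#' @export
write_camera_json <- function(camera, path) {
  jsonlite::write_json(
    list(convention = "P maps world mm (homogeneous) to image px; 1-based pixel centres, x rightward, y downward; matrix stored row-major",
         projection_row_major = as.vector(t(camera$projection)),
         image_size = camera$image_size),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(matrix(j$projection_row_major, 3, 4, byrow = TRUE),
               j$image_size)
}

#' Pipeline configuration
#'
#' Reads a YAML (or JSON) configuration and fills unset entries with the
#' documented module defaults (subset 79, step 10, ZNCC threshold 0.5,
#' smoothing window 5, minimum beat 0.4 s, prominence fraction 0.3).
#'
#' @param path YAML/JSON file; `NULL` gives the pure defaults.
#' @param overrides named list applied on top (CLI flags take precedence
#'   over the file).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    acquisition = list(frame_rate = 17, mm_per_px = 0.1),
    dic = list(subset_size = 79, step = 10, mode = "incremental",
               zncc_min = 0.5, search_range = 10),
    metrics = list(roi = NULL, extensometer = NULL, smoothing_window = 5,
                   min_beat_s = 0.4, prominence_frac = 0.3,
                   strain_reference = "first", strain_window = 3),
    simulate = list(),
    paths = list(),
    seed = 1L)
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, file_cfg)
  }
  cfg <- modify_list_deep(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

modify_list_deep <- function(a, b) {
  for (nm in names(b)) {
    if (is.list(b[[nm]]) && is.list(a[[nm]]) && !is.null(names(b[[nm]])))
      a[[nm]] <- modify_list_deep(a[[nm]], b[[nm]])
    else a[[nm]] <- b[[nm]]
  }
  a
}

#' Run the full analysis pipeline
#'
#' Chains simulate (optional) -> calibrate (stereo only) -> track per
#' camera -> stereo correspondence and 3D lift -> cardiac metrics ->
#' CSV/JSON outputs, and writes a run manifest capturing the configuration
#' snapshot, seeds, per-stage timings and warnings.  With a single camera
#' the run is 2D-only: `V_z` is absent and flagged in the manifest, never
#' zero-filled.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param sequences optional pre-loaded list with `cam1` and optionally
#'   `cam2` [image_sequence()]s (bypasses `paths`/`simulate`).
#' @return the run manifest (list), invisibly; all outputs on disk.
#' @export
run_pipeline <- function(config, out_dir, sequences = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("cardioDIC")),
                   config = unclass(config), seed = config$seed,
                   timings_s = list(), warnings = character())
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(expr), error = function(e) {
      manifest$stage_failed <<- name
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$timings_s[[name]] <<- round(proc.time()[3] - t0, 3)
    r
  }

  gt <- NULL
  cams <- NULL
  if (is.null(sequences)) {
    if (length(config$simulate) > 0) {
      sim <- config$simulate
      sequences <- stage("simulate", {
        pat <- do.call(speckle_pattern_params,
                       c(sim$pattern %||% list(), list(seed = config$seed)))
        mot <- do.call(motion_model_params,
                       c(sim$motion %||% list(), list(seed = config$seed)))
        cams <- do.call(stereo_rig, sim$rig %||% list())
        generate_stereo_sequences(pat, mot, cams,
                                  n_frames = sim$n_frames %||% 100,
                                  frame_rate = config$acquisition$frame_rate,
                                  patch_size_mm = sim$patch_size_mm %||% c(32, 32),
                                  mm_per_px = config$acquisition$mm_per_px)
      })
      gt <- sequences$ground_truth
    } else {
      sequences <- stage("load", {
        out <- list(cam1 = read_image_sequence(config$paths$cam1,
                                               config$acquisition$frame_rate,
                                               "cam1"))
        if (!is.null(config$paths$cam2))
          out$cam2 <- read_image_sequence(config$paths$cam2,
                                          config$acquisition$frame_rate,
                                          "cam2")
        out
      })
    }
  }
  stereo <- !is.null(sequences$cam2)

  if (stereo && is.null(cams)) {
    cams <- stage("calibrate", {
      if (is.null(config$paths$calibration))
        stopf("stereo run needs a calibration table (paths$calibration)")
      tab <- read.csv(config$paths$calibration)
      w <- as.matrix(tab[, c("X_mm", "Y_mm", "Z_mm")])
      sz1 <- rev(dim(sequences$cam1$frames[[1]]))
      c1 <- calibrate_dlt(w, as.matrix(tab[, c("cam1_x_px", "cam1_y_px")]), sz1)
      c2 <- calibrate_dlt(w, as.matrix(tab[, c("cam2_x_px", "cam2_y_px")]), sz1)
      write_camera_json(c1$camera, file.path(out_dir, "camera1.json"))
      write_camera_json(c2$camera, file.path(out_dir, "camera2.json"))
      manifest$calibration_rms_px <<- c(c1$rms_error, c2$rms_error)
      list(c1$camera, c2$camera)
    })
  }

  d <- dim(sequences$cam1$frames[[1]])
  roi_cfg <- config$metrics$roi %||%
    list(x0 = round(0.25 * d[2]), y0 = round(0.25 * d[1]),
         width = round(0.5 * d[2]), height = round(0.5 * d[1]))
  roi <- do.call(roi_def, roi_cfg)
  grid <- subset_grid(c(roi$x0, roi$y0, roi$width, roi$height),
                      image_size = c(d[2], d[1]),
                      subset_size = config$dic$subset_size,
                      step = config$dic$step)

  field1 <- stage("track_cam1",
                  accumulate_sequence(sequences$cam1, grid,
                                      mode = config$dic$mode,
                                      mm_per_px = config$acquisition$mm_per_px,
                                      search_range = config$dic$search_range))
  field1 <- quality_filter(field1, config$dic$zncc_min)

  field <- field1
  if (stereo) {
    field <- stage("stereo", {
      field2 <- accumulate_sequence(sequences$cam2, grid,
                                    mode = config$dic$mode,
                                    mm_per_px = config$acquisition$mm_per_px,
                                    search_range = config$dic$search_range)
      disp <- stereo_correspond(sequences$cam1$frames[[1]],
                                sequences$cam2$frames[[1]], grid,
                                cams[[1]], cams[[2]])
      lift_fields_to_3d(field1, field2, disp, cams[[1]], cams[[2]])
    })
  } else {
    note("single-camera run: V_z unavailable (2D-only, not zero-filled)")
  }
  write_field_csv(field, file.path(out_dir, "field.csv"))

  metrics <- stage("analyze", {
    tr <- roi_traces(field, roi)
    beats <- segment_beats(tr$V_l, config$metrics$min_beat_s,
                           config$metrics$prominence_frac)
    tv <- tissue_velocity(tr$V_l, config$metrics$smoothing_window)
    tvp <- detect_tv_points(tv, beats)
    strain <- local_strain_field(field, config$metrics$strain_window,
                                 roi = roi,
                                 reference = config$metrics$strain_reference,
                                 beats = beats)
    ext_cfg <- config$metrics$extensometer
    ext <- if (!is.null(ext_cfg)) extensometer_def(ext_cfg$p1, ext_cfg$p2)
    else extensometer_def(c(roi$x0 + roi$width / 2, roi$y0 + 2),
                          c(roi$x0 + roi$width / 2, roi$y0 + roi$height - 2))
    L <- extensometer_length(field, ext)
    fs <- fractional_shortening(L, beats)
    sr <- strain_and_rate(L, beats, config$metrics$smoothing_window)
    dirs <- directional_strains(field, ext)
    list(traces = tr, beats = beats, tv = tv, tv_points = tvp,
         strain = strain, L = L, fs = fs, strain_rate = sr,
         directional = dirs, roi = roi, extensometer = ext)
  })

  stage("export", {
    write_trace_csv(metrics$traces, file.path(out_dir, "vector_components.csv"))
    write_trace_csv(metrics$tv, file.path(out_dir, "tissue_velocity.csv"))
    write_trace_csv(metrics$fs, file.path(out_dir, "fractional_shortening.csv"))
    write_trace_csv(list(metrics$strain_rate$strain,
                         metrics$strain_rate$strain_rate),
                    file.path(out_dir, "strain_and_rate.csv"))
    write_trace_csv(metrics$directional, file.path(out_dir, "directional_strains.csv"))
    write.csv(metrics$strain$per_frame,
              file.path(out_dir, "principal_strains.csv"), row.names = FALSE)
    pts <- merge(metrics$tv_points, metrics$strain_rate$points, by = "beat")
    write.csv(pts, file.path(out_dir, "characteristic_points.csv"),
              row.names = FALSE)
    write.csv(data.frame(beat = seq_len(nrow(metrics$beats$intervals)),
                         start_frame = metrics$beats$intervals[, 1],
                         end_frame = metrics$beats$intervals[, 2]),
              file.path(out_dir, "beats.csv"), row.names = FALSE)
    if (!is.null(gt))
      write_ground_truth_csv(gt, file.path(out_dir, "ground_truth.csv"))
  })

  manifest$n_frames <- length(sequences$cam1$frames)
  manifest$n_points <- nrow(grid$centers)
  manifest$n_beats <- nrow(metrics$beats$intervals)
  manifest$stereo <- stereo
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(manifest, list(metrics = metrics, field = field)))
}

#' Plot the standard report figures
#'
#' Writes PNG analogues of the standard trace figures (vector components,
#' principal strains, tissue velocity, fractional shortening, strain and
#' strain rate, directional strains) from a pipeline output directory.
#'
#' @param analysis_dir directory written by [run_pipeline()].
#' @param out_dir where to place the PNGs (defaults to `analysis_dir`).
#' @return character vector of files written, invisibly.
#' @export
report_figures <- function(analysis_dir, out_dir = analysis_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  plot_csv <- function(file, png_name, ylab) {
    p <- file.path(analysis_dir, file)
    if (!file.exists(p)) return()
    df <- read.csv(p)
    out <- file.path(out_dir, png_name)
    grDevices::png(out, width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    labs <- unique(df$label)
    graphics::matplot(matrix(df$time_s, ncol = length(labs)),
                      matrix(df$value, ncol = length(labs)),
                      type = "l", lty = 1, xlab = "time (s)", ylab = ylab)
    graphics::legend("topright", legend = labs, col = seq_along(labs), lty = 1)
    written <<- c(written, out)
  }
  plot_csv("vector_components.csv", "vector_components.png", "mm")
  plot_csv("tissue_velocity.csv", "tissue_velocity.png", "cm/s")
  plot_csv("fractional_shortening.csv", "fractional_shortening.png", "FS (%)")
  plot_csv("strain_and_rate.csv", "strain_and_rate.png", "strain (%) / rate (1/s)")
  plot_csv("directional_strains.csv", "directional_strains.png", "strain (%)")
  p <- file.path(analysis_dir, "principal_strains.csv")
  if (file.exists(p)) {
    df <- read.csv(p)
    out <- file.path(out_dir, "principal_strains.png")
    grDevices::png(out, width = 900, height = 500)
    graphics::matplot(df$time, cbind(df$e_max, df$e_min), type = "l", lty = 1,
                      xlab = "time (s)", ylab = "principal strain (%)")
    graphics::legend("topright", legend = c("e_max", "e_min"),
                     col = 1:2, lty = 1)
    grDevices::dev.off()
    written <- c(written, out)
  }
  invisible(written)
}
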