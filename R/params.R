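#' Speckle pattern parameters
#'
#' Describes the random dot pattern drawn on the tracked surface: dark dots
#' on a light background (an inverse speckle pattern, as produced by a
#' sterile marker on pale epicardial fat).
#'
#' @param dot_density dots per mm^2.
#' @param dot_radius_mean,dot_radius_sd dot radius distribution, mm.
#' @param dot_intensity,background_intensity gray levels of dots and
#'   background; must lie within the bit depth.
#' @param blur_sigma Gaussian blur applied after rasterisation, px.
#' @param noise_sigma additive Gaussian image noise per frame, gray levels.
#' @param bit_depth image bit depth (8 or 16).
#' @param seed integer RNG seed; identical seed gives an identical pattern.
#' @return An object of class `speckle_pattern_params`.
#' @export
speckle_pattern_params <- function(dot_density = 2,
                                   dot_radius_mean = 0.3,
                                   dot_radius_sd = 0.06,
                                   dot_intensity = 30,
                                   background_intensity = 220,
                                   blur_sigma = 0.8,
                                   noise_sigma = 2,
                                   bit_depth = 8,
                                   seed = 1L) {
  check_scalar(dot_density, "dot_density", lower = 0)
  check_scalar(dot_radius_mean, "dot_radius_mean", lower = 0,
               strict_lower = TRUE)
  check_scalar(dot_radius_sd, "dot_radius_sd", lower = 0)
  if (!bit_depth %in% c(8, 16))
    stopf("invalid-parameter: bit_depth must be 8 or 16")
  imax <- 2^bit_depth - 1
  check_scalar(dot_intensity, "dot_intensity", lower = 0, upper = imax)
  check_scalar(background_intensity, "background_intensity",
               lower = 0, upper = imax)
  check_scalar(blur_sigma, "blur_sigma", lower = 0)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  structure(list(dot_density = dot_density,
                 dot_radius_mean = dot_radius_mean,
                 dot_radius_sd = dot_radius_sd,
                 dot_intensity = dot_intensity,
                 background_intensity = background_intensity,
                 blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma,
                 bit_depth = bit_depth,
                 seed = as.integer(seed)),
            class = "speckle_pattern_params")
}

#' Analytic cardiac motion model parameters
#'
#' The synthetic heart surface moves as a superposition of rigid-body
#' translation and homogeneous (affine) contraction about a centre, with an
#' out-of-plane component and a slow respiration-driven amplitude
#' modulation.  The beat waveform has four clinically named phases:
#' systolic contraction, early-diastolic (E) recovery, diastasis plateau,
#' and the atrial (A) kick completing relaxation.
#'
#' @param heart_rate beats per minute.
#' @param systole_fraction fraction of the beat period spent in systolic
#'   contraction (0-1).
#' @param early_diastole_fraction fraction spent in early-diastolic
#'   recovery.
#' @param early_recovery_ratio fraction of the contraction recovered during
#'   early diastole (0-1); the remainder is recovered by the atrial kick.
#' @param atrial_fraction fraction of the period occupied by the atrial
#'   kick at the end of the cycle; the diastasis plateau fills the gap
#'   between early diastole and the kick.
#' @param contraction_amplitude peak relative shortening `a` of the surface
#'   about the centre (dimensionless, 0 < a < 1; 0 allowed for a static
#'   contraction test).
#' @param anisotropy length-2 multiplier of `a` per in-plane axis.
#' @param translation_amplitude length-3 rigid translation amplitudes
#'   (x, y, z), mm; the z component is the out-of-plane motion.
#' @param respiration_rate breaths per minute.
#' @param respiration_mod_depth relative amplitude modulation depth imposed
#'   by respiration (0 disables it).
#' @param center in-plane coordinates of the contraction centre, mm (world
#'   frame).
#' @param n_beats number of heartbeats the sequence should span.
#' @param seed integer RNG seed.
#' @return An object of class `motion_model_params`.
#' @export
motion_model_params <- function(heart_rate = 60,
                                systole_fraction = 0.30,
                                early_diastole_fraction = 0.20,
                                early_recovery_ratio = 0.80,
                                atrial_fraction = 0.25,
                                contraction_amplitude = 0.2,
                                anisotropy = c(1, 1),
                                translation_amplitude = c(14, -8, 10),
                                respiration_rate = 12,
                                respiration_mod_depth = 0.08,
                                center = c(0, 0),
                                n_beats = 5L,
                                seed = 1L) {
  check_scalar(heart_rate, "heart_rate", lower = 0, strict_lower = TRUE)
  check_scalar(systole_fraction, "systole_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(early_diastole_fraction, "early_diastole_fraction",
               lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(early_recovery_ratio, "early_recovery_ratio",
               lower = 0, upper = 1)
  check_scalar(atrial_fraction, "atrial_fraction", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (systole_fraction + early_diastole_fraction >= 1)
    stopf("invalid-parameter: systole_fraction + early_diastole_fraction must be < 1")
  if (systole_fraction + early_diastole_fraction + atrial_fraction > 1)
    stopf("invalid-parameter: beat phases exceed one period")
  check_scalar(contraction_amplitude, "contraction_amplitude",
               lower = 0, upper = 1, strict_upper = TRUE)
  if (length(anisotropy) != 2L || !all(is.finite(anisotropy)))
    stopf("invalid-parameter: anisotropy must be length-2 finite numeric")
  if (length(translation_amplitude) != 3L || !all(is.finite(translation_amplitude)))
    stopf("invalid-parameter: translation_amplitude must be length-3 finite numeric")
  check_scalar(respiration_rate, "respiration_rate", lower = 0)
  check_scalar(respiration_mod_depth, "respiration_mod_depth", lower = 0)
  if (length(center) != 2L || !all(is.finite(center)))
    stopf("invalid-parameter: center must be length-2 finite numeric")
  check_scalar(n_beats, "n_beats", lower = 1)
  structure(list(heart_rate = heart_rate,
                 systole_fraction = systole_fraction,
                 early_diastole_fraction = early_diastole_fraction,
                 early_recovery_ratio = early_recovery_ratio,
                 atrial_fraction = atrial_fraction,
                 contraction_amplitude = contraction_amplitude,
                 anisotropy = as.numeric(anisotropy),
                 translation_amplitude = as.numeric(translation_amplitude),
                 respiration_rate = respiration_rate,
                 respiration_mod_depth = respiration_mod_depth,
                 center = as.numeric(center),
                 n_beats = as.integer(n_beats),
                 seed = as.integer(seed)),
            class = "motion_model_params")
}

#' @export
print.speckle_pattern_params <- function(x, ...) {
  cat("Speckle pattern:", x$dot_density, "dots/mm^2, radius",
      x$dot_radius_mean, "+/-", x$dot_radius_sd, "mm,",
      x$dot_intensity, "on", x$background_intensity,
      sprintf("(%d-bit), blur %.2g px, noise %.2g, seed %d\n",
              x$bit_depth, x$blur_sigma, x$noise_sigma, x$seed))
  invisible(x)
}

#' @export
print.motion_model_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Cardiac motion model: %g bpm, a = %g (anisotropy %g/%g), phases",
    " s/e/plateau/a = %.2f/%.2f/%.2f/%.2f of the period,\n",
    "  translation (%g, %g, %g) mm, respiration %g /min (depth %g),",
    " %d beats, seed %d\n"),
    x$heart_rate, x$contraction_amplitude, x$anisotropy[1], x$anisotropy[2],
    x$systole_fraction, x$early_diastole_fraction,
    1 - x$systole_fraction - x$early_diastole_fraction - x$atrial_fraction,
    x$atrial_fraction,
    x$translation_amplitude[1], x$translation_amplitude[2],
    x$translation_amplitude[3],
    x$respiration_rate, x$respiration_mod_depth, x$n_beats, x$seed))
  invisible(x)
}
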