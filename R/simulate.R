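#' Transmission measurement protocol
#'
#' Describes one synthetic attenuation experiment: absorber thicknesses,
#' tube voltages, repeat count, unattenuated kerma rate, and the
#' multiplicative noise level. Defaults follow the bench protocol the
#' simulator emulates: nominal thicknesses 0 to 5 cm in 0.5 cm steps,
#' tube voltages 50 to 120 kV in 10 kV steps, three exposures per point.
#'
#' @param thicknesses Non-negative, strictly increasing thicknesses in cm;
#'   must include 0.
#' @param tube_voltages Tube voltages in kV.
#' @param repeats Number of repeated exposures per point (>= 1).
#' @param kerma_at_zero Unattenuated air-kerma rate, mGy/min.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise (>= 0). The default 0.01 is a plausible dosimeter
#'   repeatability, not a measured value.
#' @param seed Integer master seed; split into per-voltage substreams.
#' @return An object of class `transmission_protocol`.
#' @export
transmission_protocol <- function(thicknesses = seq(0, 5, by = 0.5),
                                  tube_voltages = seq(50, 120, by = 10),
                                  repeats = 3,
                                  kerma_at_zero = 30,
                                  noise_cv = 0.01,
                                  seed = 1L) {
  thicknesses <- as.numeric(thicknesses)
  if (any(thicknesses < 0) || is.unsorted(thicknesses, strictly = TRUE))
    stop_radqc("thicknesses must be non-negative and strictly increasing",
               class = "radqc_invalid_protocol")
  if (!any(thicknesses == 0))
    stop_radqc("thicknesses must include 0", class = "radqc_invalid_protocol")
  if (repeats < 1)
    stop_radqc("repeats must be >= 1", class = "radqc_invalid_protocol")
  if (noise_cv < 0)
    stop_radqc("noise_cv must be >= 0", class = "radqc_invalid_protocol")
  if (kerma_at_zero <= 0)
    stop_radqc("kerma_at_zero must be positive", class = "radqc_invalid_protocol")
  structure(list(thicknesses = thicknesses,
                 tube_voltages = as.numeric(tube_voltages),
                 repeats = as.integer(repeats),
                 kerma_at_zero = kerma_at_zero,
                 noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "transmission_protocol")
}

#' Built-in per-voltage spectrum models
#'
#' Two-component spectra (equal weights, attenuation-coefficient ratio 2.5)
#' calibrated so that the model's ground-truth specimen HVL equals the
#' bundled clear-specimen reference HVL at each voltage, and likewise for
#' the aluminum coefficients against the reported aluminum HVLs. Voltages
#' between table entries are served by linear interpolation of the target
#' HVLs. The ratio-2.5 split gives the curvature (beam hardening) of a
#' realistic polyenergetic transmission curve while staying identifiable
#' from 11 thickness points.
#'
#' @param tube_voltages Voltages (kV) within 50-120.
#' @param mu_ratio Ratio of fast to slow component coefficient (> 1).
#' @param weight Weight of the fast component, in (0, 1).
#' @return Named list of [spectrum_model()] objects, names = voltages.
#' @export
#' @examples
#' models <- default_spectra(c(50, 120))
#' ground_truth_hvl(models[["50"]], unit = "mm")  # 20.1
default_spectra <- function(tube_voltages = seq(50, 120, by = 10),
                            mu_ratio = 2.5, weight = 0.5) {
  stopifnot(mu_ratio > 1, weight > 0, weight < 1)
  ref <- reference_beam_quality()
  if (any(tube_voltages < min(ref$tube_voltage_kv)) ||
      any(tube_voltages > max(ref$tube_voltage_kv)))
    stop_radqc("tube voltages must lie within the calibrated 50-120 kV range",
               class = "radqc_invalid_protocol")
  hvl_cm <- stats::approx(ref$tube_voltage_kv, ref$hvl_specimen_mm / 10,
                          xout = tube_voltages)$y
  hvl_al <- stats::approx(ref$tube_voltage_kv, ref$hvl_al_mm,
                          xout = tube_voltages)$y
  models <- lapply(seq_along(tube_voltages), function(i) {
    mu1 <- calibrate_two_component(hvl_cm[i], mu_ratio, weight)
    mu1_al <- calibrate_two_component(hvl_al[i], mu_ratio, weight)
    spectrum_model(c(weight, 1 - weight),
                   mu_specimen = c(mu1, mu1 / mu_ratio),
                   mu_reference = c(mu1_al, mu1_al / mu_ratio),
                   description = sprintf("%g kV (calibrated)", tube_voltages[i]))
  })
  stats::setNames(models, as.character(tube_voltages))
}

# Solve for the fast-component coefficient so that the two-component model
# w e^{-mu1 h} + (1-w) e^{-mu1 h / r} = 1/2 at the target half-value h.
calibrate_two_component <- function(hvl, mu_ratio, weight) {
  f <- function(mu1) {
    weight * exp(-mu1 * hvl) + (1 - weight) * exp(-mu1 * hvl / mu_ratio) - 0.5
  }
  hi <- log(2) / hvl * mu_ratio
  while (f(hi) > 0) hi <- hi * 2
  bisect_root(f, 0, hi, tol = 1e-13)
}

#' Simulate a transmission experiment
#'
#' For each tube voltage and thickness, draws `repeats` air-kerma-rate
#' readings
#' \deqn{K = K_0 \, T(t) \, (1 + \varepsilon), \quad
#'       \varepsilon \sim N(0, \mathrm{cv}^2),}
#' with \eqn{T} the model transmission. Noise is multiplicative (dosimeter
#' readings are positive with roughly constant relative error); draws with
#' \eqn{\varepsilon < -0.99} are resampled so readings stay strictly
#' positive. Each voltage uses an independent substream of the master seed,
#' keyed by the voltage value, so subsetting `tube_voltages` leaves other
#' voltages' readings unchanged. Equal seeds give bit-identical output.
#'
#' @param protocol A [transmission_protocol()].
#' @param models Named list of [spectrum_model()] objects keyed by voltage
#'   (as in [default_spectra()]). Every protocol voltage must be present.
#' @return An object of class `transmission_experiment`: a list with
#'   `series` (list of [transmission_series()] objects) and `truth`
#'   (data.frame of ground-truth specimen HVLs in mm per voltage, obtained
#'   from each model by bisection), plus the protocol.
#' @export
simulate_transmission_experiment <- function(protocol,
                                             models = default_spectra(protocol$tube_voltages)) {
  stopifnot(inherits(protocol, "transmission_protocol"))
  kvs <- protocol$tube_voltages
  missing_kv <- setdiff(as.character(kvs), names(models))
  if (length(missing_kv) > 0)
    stop_radqc("no spectrum model for tube voltage(s): ",
               paste(missing_kv, collapse = ", "),
               class = "radqc_missing_model")
  series <- vector("list", length(kvs))
  truth <- data.frame(tube_voltage_kv = kvs, hvl_true_mm = NA_real_,
                      hvl_al_true_mm = NA_real_)
  for (i in seq_along(kvs)) {
    model <- models[[as.character(kvs[i])]]
    trans <- spectrum_transmission(model, protocol$thicknesses)
    ideal <- protocol$kerma_at_zero * trans
    n_t <- length(protocol$thicknesses)
    kerma <- with_seed(substream_seed(protocol$seed, kvs[i]), {
      eps <- matrix(rnorm(n_t * protocol$repeats, 0, protocol$noise_cv),
                    nrow = n_t)
      while (any(bad <- eps < -0.99))
        eps[bad] <- rnorm(sum(bad), 0, protocol$noise_cv)
      ideal * (1 + eps)
    })
    truth$hvl_true_mm[i] <- ground_truth_hvl(model, unit = "mm")
    truth$hvl_al_true_mm[i] <- ground_truth_hvl(model, material = "reference")
    series[[i]] <- transmission_series(
      tube_voltage = kvs[i],
      thicknesses = protocol$thicknesses,
      kerma = kerma,
      hvl_al_reported = truth$hvl_al_true_mm[i])
  }
  structure(list(series = series, truth = truth, protocol = protocol),
            class = "transmission_experiment")
}

#' Projection scene configuration for the perpendicularity tool
#'
#' Geometry of one synthetic radiograph of the marker platform: a square
#' platform (default 10 cm across, 20 cm tall) carrying four vertically
#' aligned marker pairs at its corners and one central fiducial on top,
#' imaged by a point source. The detector plane is z = 0 with x/y in mm;
#' the source sits at height `sid` above `source_foot` (the true
#' perpendicular-ray location). Bottom markers default to 2 mm above the
#' detector (platform base plate).
#'
#' @param source_foot (x, y) of the source's foot on the detector, mm.
#' @param sid Source-image distance, mm.
#' @param platform_center (x, y) of the platform center on the detector, mm.
#' @param platform_half_width Half the platform side, mm (default 50).
#' @param platform_height Height of the top markers, mm (default 200).
#' @param bottom_marker_height Height of the bottom markers, mm.
#' @param pixel_spacing Detector pixel pitch, mm/pixel.
#' @param localization_noise_sd Gaussian sd (mm) added to each projected
#'   coordinate, emulating marker-centroid localization error.
#' @param seed Integer master seed; split per marker.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(source_foot = c(0, 0), sid = 1000,
                         platform_center = c(0, 0),
                         platform_half_width = 50, platform_height = 200,
                         bottom_marker_height = 2,
                         pixel_spacing = 0.143,
                         localization_noise_sd = 0, seed = 1L) {
  if (!(sid > platform_height))
    stop_radqc("sid must exceed platform_height (marker at/above source)",
               class = "radqc_invalid_scene")
  if (!(platform_height > bottom_marker_height) || bottom_marker_height < 0)
    stop_radqc("need sid > platform_height > bottom_marker_height >= 0",
               class = "radqc_invalid_scene")
  if (pixel_spacing <= 0)
    stop_radqc("pixel_spacing must be positive", class = "radqc_invalid_scene")
  if (localization_noise_sd < 0)
    stop_radqc("localization_noise_sd must be >= 0",
               class = "radqc_invalid_scene")
  structure(list(source_foot = as.numeric(source_foot), sid = sid,
                 platform_center = as.numeric(platform_center),
                 platform_half_width = platform_half_width,
                 platform_height = platform_height,
                 bottom_marker_height = bottom_marker_height,
                 pixel_spacing = pixel_spacing,
                 localization_noise_sd = localization_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Central projection of a point at (xy, z) through the source onto z = 0.
project_point <- function(xy, z, source_foot, sid) {
  if (z >= sid)
    stop_radqc("marker at or above source height", class = "radqc_invalid_scene")
  source_foot + (xy - source_foot) * sid / (sid - z)
}

#' Simulate a perpendicularity-tool radiograph
#'
#' Projects the eight corner markers (four vertical pairs at the platform
#' corners) and the central top fiducial through the point source onto the
#' detector plane by similar triangles, then adds seeded Gaussian
#' localization noise to each projected coordinate (independent substream
#' per marker). In a noiseless scene the line through each pair's two
#' projections passes exactly through the source foot, which is the
#' geometric fact the perpendicularity tool exploits.
#'
#' @param config A [scene_config()].
#' @return An object of class `projection_scene`: list with `observations`
#'   (list of [marker_pair_observation()] in mm), `central_fiducial`
#'   (projected (x, y) mm of the top-center marker), `truth` (list with
#'   `source_foot`, `sid`, and the exact top-plane magnification
#'   sid / (sid - platform_height)), and the config.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  hw <- config$platform_half_width
  corners <- list(NE = c(hw, hw), NW = c(-hw, hw),
                  SW = c(-hw, -hw), SE = c(hw, -hw))
  noise <- function(key, xy) {
    if (config$localization_noise_sd == 0) return(xy)
    xy + with_seed(substream_seed(config$seed, key),
                   rnorm(2, 0, config$localization_noise_sd))
  }
  obs <- vector("list", 4L)
  for (i in seq_along(corners)) {
    xy <- config$platform_center + corners[[i]]
    top <- project_point(xy, config$platform_height,
                         config$source_foot, config$sid)
    bottom <- project_point(xy, config$bottom_marker_height,
                            config$source_foot, config$sid)
    obs[[i]] <- marker_pair_observation(names(corners)[i],
                                        top = noise(2L * i - 1L, top),
                                        bottom = noise(2L * i, bottom))
  }
  central <- noise(9L, project_point(config$platform_center,
                                     config$platform_height,
                                     config$source_foot, config$sid))
  structure(list(observations = obs,
                 central_fiducial = central,
                 truth = list(source_foot = config$source_foot,
                              sid = config$sid,
                              magnification_top =
                                config$sid / (config$sid - config$platform_height)),
                 config = config),
            class = "projection_scene")
}
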