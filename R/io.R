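#' Write a transmission experiment to CSV (+ ground-truth sidecar)
#'
#' Writes the long-format measurement table (columns `kV`, `thickness_cm`,
#' `repeat_index`, `kerma_mGy_min`, `hvl_al_mm`) and, for simulated
#' experiments, a `ground_truth.json` sidecar with the per-voltage true
#' HVLs and the seed. Fixed CSV dialect: comma separator, "." decimal,
#' header row, UTF-8. Units live in the column names.
#'
#' @param experiment A `transmission_experiment` (from
#'   [simulate_transmission_experiment()]) or plain list of
#'   [transmission_series()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the measurement CSV path.
#' @export
write_transmission_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- if (inherits(experiment, "transmission_experiment"))
    experiment$series else experiment
  rows <- lapply(series, function(s) {
    n_t <- length(s$thicknesses); n_r <- ncol(s$kerma)
    data.frame(kV = s$tube_voltage,
               thickness_cm = rep(s$thicknesses, times = n_r),
               repeat_index = rep(seq_len(n_r), each = n_t),
               kerma_mGy_min = as.vector(s$kerma),
               hvl_al_mm = s$hvl_al_reported)
  })
  path <- file.path(dir, "measurements.csv")
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (inherits(experiment, "transmission_experiment")) {
    jsonlite::write_json(
      list(seed = experiment$protocol$seed,
           noise_cv = experiment$protocol$noise_cv,
           kerma_at_zero = experiment$protocol$kerma_at_zero,
           truth = experiment$truth),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a transmission measurement CSV
#'
#' Expects columns `kV`, `thickness_cm`, `repeat_index`, `kerma_mGy_min`
#' and optionally `hvl_al_mm` (constant within each voltage). Row order is
#' irrelevant; rows are grouped by voltage into [transmission_series()].
#' Validation failures (missing columns, non-numeric cells, non-positive
#' kerma, duplicate (kV, thickness, repeat) keys) raise errors naming the
#' offending rows.
#'
#' @param path CSV file path.
#' @param areal_density_per_article Optional per-article areal density
#'   (g/cm2) attached to every series for HVD computation.
#' @param article_thickness_cm Nominal article thickness, cm.
#' @return List of [transmission_series()], sorted by voltage.
#' @export
read_measurement_csv <- function(path, areal_density_per_article = NULL,
                                 article_thickness_cm = 0.5) {
  if (!file.exists(path))
    stop_radqc("input file does not exist: ", path, class = "radqc_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("kV", "thickness_cm", "repeat_index", "kerma_mGy_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_radqc("missing column(s): ", paste(miss, collapse = ", "),
               class = "radqc_io_error")
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop_radqc("non-numeric or missing '", col, "' at row(s): ",
                 paste(utils::head(bad + 1L, 5L), collapse = ", "),
                 class = "radqc_io_error")
    df[[col]] <- v
  }
  bad_k <- which(df$kerma_mGy_min <= 0)
  if (length(bad_k))
    stop_radqc("non-positive kerma at row(s): ",
               paste(utils::head(bad_k + 1L, 5L), collapse = ", "),
               class = "radqc_io_error")
  key <- paste(df$kV, df$thickness_cm, df$repeat_index)
  if (anyDuplicated(key))
    stop_radqc("duplicate (kV, thickness, repeat) at row(s): ",
               paste(utils::head(which(duplicated(key)) + 1L, 5L),
                     collapse = ", "),
               class = "radqc_io_error")
  lapply(sort(unique(df$kV)), function(kv) {
    sub <- df[df$kV == kv, , drop = FALSE]
    thicknesses <- sort(unique(sub$thickness_cm))
    reps <- sort(unique(sub$repeat_index))
    kerma <- matrix(NA_real_, length(thicknesses), length(reps))
    for (r in seq_along(reps)) {
      s2 <- sub[sub$repeat_index == reps[r], , drop = FALSE]
      kerma[match(s2$thickness_cm, thicknesses), r] <- s2$kerma_mGy_min
    }
    if (anyNA(kerma))
      stop_radqc("incomplete thickness x repeat grid for ", kv, " kV",
                 class = "radqc_io_error")
    hvl_al <- if ("hvl_al_mm" %in% names(sub))
      unique(as.numeric(sub$hvl_al_mm))[1L] else NA_real_
    transmission_series(kv, thicknesses, kerma, hvl_al_reported = hvl_al,
                        areal_density_per_article = areal_density_per_article,
                        article_thickness_cm = article_thickness_cm)
  })
}

#' Write a projection scene's marker observations to CSV
#'
#' Long format: `pair_label`, `end` (top|bottom), `x_px`, `y_px`, with the
#' pixel spacing recorded in a leading `# pixel_spacing_mm <value>` comment
#' line. Coordinates are converted from mm with the origin at the image
#' center.
#'
#' @param scene A `projection_scene` from [simulate_scene()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_marker_csv <- function(scene, path) {
  stopifnot(inherits(scene, "projection_scene"))
  sp <- scene$config$pixel_spacing
  rows <- do.call(rbind, lapply(scene$observations, function(o) {
    px_t <- mm_to_pixels(o$top, sp)
    px_b <- mm_to_pixels(o$bottom, sp)
    data.frame(pair_label = o$label,
               end = c("top", "bottom"),
               x_px = c(px_t[1L], px_b[1L]),
               y_px = c(px_t[2L], px_b[2L]))
  }))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pixel_spacing_mm %.10g", sp), con)
  write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Read marker observations from CSV
#'
#' Reads the dialect written by [write_marker_csv()] and converts to mm.
#' The pixel spacing comes from the `# pixel_spacing_mm` header line unless
#' overridden.
#'
#' @param path CSV path.
#' @param pixel_spacing Override for the header value, mm/pixel.
#' @param image_center Image center in pixels (origin of the mm frame).
#' @return List of [marker_pair_observation()] in mm.
#' @export
read_marker_csv <- function(path, pixel_spacing = NULL,
                            image_center = c(0, 0)) {
  if (!file.exists(path))
    stop_radqc("input file does not exist: ", path, class = "radqc_io_error")
  first <- readLines(path, n = 1L)
  if (is.null(pixel_spacing)) {
    m <- regmatches(first, regexec("^#\\s*pixel_spacing_mm\\s+([0-9.eE+-]+)",
                                   first))[[1L]]
    if (length(m) < 2L)
      stop_radqc("pixel spacing not found in header; pass pixel_spacing=",
                 class = "radqc_io_error")
    pixel_spacing <- as.numeric(m[2L])
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pair_label", "end", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_radqc("missing column(s): ", paste(miss, collapse = ", "),
               class = "radqc_io_error")
  lapply(unique(df$pair_label), function(lab) {
    sub <- df[df$pair_label == lab, , drop = FALSE]
    get_end <- function(e) {
      r <- sub[sub$end == e, , drop = FALSE]
      if (nrow(r) != 1L)
        stop_radqc("pair '", lab, "' needs exactly one '", e, "' row",
                   class = "radqc_io_error")
      pixels_to_mm(c(r$x_px, r$y_px), pixel_spacing, image_center)
    }
    marker_pair_observation(lab, top = get_end("top"),
                            bottom = get_end("bottom"))
  })
}

#' Write pipeline results to an output directory
#'
#' Deterministic file set given the results: `beam_quality.csv` +
#' `fits.json` + `trend.json` for the attenuation pipeline,
#' `perp_result.json` for the perpendicularity pipeline, and a `run.log`
#' echoing the configuration. Payload files contain no timestamps, so two
#' runs with identical inputs are byte-identical (timestamps only in the
#' log).
#'
#' @param results List from [run_attenuation_pipeline()] or
#'   [run_perpendicularity_pipeline()] (or a compatible subset).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(results$beam_quality)) {
    p <- file.path(dir, "beam_quality.csv")
    write.csv(results$beam_quality, p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(results$fits)) {
    p <- file.path(dir, "fits.json")
    jsonlite::write_json(
      lapply(results$fits, function(f)
        f[c("a1", "m1", "a2", "m2", "rmse", "converged", "attenuating")]),
      p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  if (!is.null(results$trend)) {
    p <- file.path(dir, "trend.json")
    jsonlite::write_json(results$trend, p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  if (!is.null(results$perp)) {
    p <- file.path(dir, "perp_result.json")
    r <- results$perp
    jsonlite::write_json(
      list(perp_ray = r$perp_ray, method = r$method,
           per_line_residuals = r$per_line_residuals,
           deviations = as.list(r$deviations)),
      p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  log_path <- file.path(dir, "run.log")
  writeLines(c(sprintf("radqc run at %s", format(Sys.time())),
               sprintf("config: %s",
                       jsonlite::toJSON(results$config, auto_unbox = TRUE))),
             log_path)
  invisible(c(written, log_path))
}

#' Attenuation study pipeline
#'
#' read -> average -> double-exponential fit -> HVL / HVD / mu ->
#' quadratic voltage trends -> cross-material line -> report files.
#'
#' @param measurements_csv Input CSV (see [read_measurement_csv()]).
#' @param out_dir Output directory; NULL skips file output.
#' @param areal_density_per_article Optional g/cm2 per article (enables
#'   HVD).
#' @param article_thickness_cm Nominal article thickness, cm.
#' @return Invisibly, list with `beam_quality` (data.frame), `fits`,
#'   `trend` (quadratic coefficient sets, plus the cross-material line
#'   when aluminum HVLs are present), `config`.
#' @export
run_attenuation_pipeline <- function(measurements_csv, out_dir = NULL,
                                     areal_density_per_article = NULL,
                                     article_thickness_cm = 0.5) {
  series <- read_measurement_csv(measurements_csv,
                                 areal_density_per_article,
                                 article_thickness_cm)
  fits <- lapply(series, function(s)
    fit_double_exponential(average_repeats(s)))
  names(fits) <- vapply(series, function(s) as.character(s$tube_voltage),
                        character(1))
  tab <- build_beam_quality_table(series, fits)
  trend <- list()
  if (nrow(tab) >= 3L) {
    qt <- fit_quadratic_trend(tab$tube_voltage_kv, tab$hvl_specimen_mm / 10,
                              y_kind = "hvl_cm")
    trend$hvl <- list(a = qt$a, b = qt$b, c = qt$c, y_kind = qt$y_kind)
    if (!anyNA(tab$hvd_g_cm2)) {
      qd <- fit_quadratic_trend(tab$tube_voltage_kv, tab$hvd_g_cm2,
                                y_kind = "hvd_g_cm2")
      trend$hvd <- list(a = qd$a, b = qd$b, c = qd$c, y_kind = qd$y_kind)
    }
  }
  if (!anyNA(tab$hvl_al_mm) && length(unique(tab$hvl_al_mm)) >= 2L) {
    cf <- fit_cross_material_line(tab$hvl_al_mm, tab$hvl_specimen_mm)
    trend$cross_material <- list(slope = cf$slope, intercept = cf$intercept)
  }
  results <- list(beam_quality = tab, fits = fits, trend = trend,
                  config = list(pipeline = "attenuation",
                                input = measurements_csv,
                                areal_density_per_article =
                                  areal_density_per_article,
                                article_thickness_cm = article_thickness_cm))
  if (!is.null(out_dir)) write_report(results, out_dir)
  invisible(results)
}

#' Perpendicularity analysis pipeline
#'
#' read markers -> lines through pairs -> locate perpendicular ray ->
#' deviation distances -> report files.
#'
#' @param markers_csv Input CSV (see [read_marker_csv()]).
#' @param out_dir Output directory; NULL skips file output.
#' @param detector_center Detector center, mm (default origin).
#' @param light_field_center,central_ray Optional reference points, mm.
#' @param method Estimator passed to [locate_perpendicular_ray()].
#' @param pixel_spacing Optional override for the CSV header value.
#' @return Invisibly, list with `perp` (a `perpendicularity_result`) and
#'   `config`.
#' @export
run_perpendicularity_pipeline <- function(markers_csv, out_dir = NULL,
                                          detector_center = c(0, 0),
                                          light_field_center = NULL,
                                          central_ray = NULL,
                                          method = "least_squares",
                                          pixel_spacing = NULL) {
  obs <- read_marker_csv(markers_csv, pixel_spacing = pixel_spacing)
  lines <- lapply(obs, line_through_pair)
  result <- locate_perpendicular_ray(lines, method = method)
  result <- deviation_report(result, detector_center,
                             light_field_center = light_field_center,
                             central_ray = central_ray)
  results <- list(perp = result,
                  config = list(pipeline = "perpendicularity",
                                input = markers_csv, method = method,
                                detector_center = detector_center))
  if (!is.null(out_dir)) write_report(results, out_dir)
  invisible(results)
}
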