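#' Convert pixel coordinates to detector millimetres
#'
#' Millimetre coordinates are measured from the image center:
#' `(p - image_center) * pixel_spacing` per axis. Invertible via
#' [mm_to_pixels()].
#'
#' @param coords Numeric 2-vector or n x 2 matrix of pixel coordinates.
#' @param pixel_spacing Pixel pitch, mm/pixel (> 0).
#' @param image_center Pixel coordinates of the image center.
#' @return Coordinates in mm, same shape as input.
#' @export
pixels_to_mm <- function(coords, pixel_spacing, image_center = c(0, 0)) {
  if (pixel_spacing <= 0)
    stop_radqc("pixel_spacing must be positive", class = "radqc_invalid_scene")
  if (is.matrix(coords))
    sweep(coords, 2L, image_center) * pixel_spacing
  else (coords - image_center) * pixel_spacing
}

#' @rdname pixels_to_mm
#' @export
mm_to_pixels <- function(coords, pixel_spacing, image_center = c(0, 0)) {
  if (pixel_spacing <= 0)
    stop_radqc("pixel_spacing must be positive", class = "radqc_invalid_scene")
  if (is.matrix(coords))
    sweep(coords / pixel_spacing, 2L, image_center, `+`)
  else coords / pixel_spacing + image_center
}

#' Projected positions of one vertically aligned marker pair
#'
#' @param label Pair label (e.g. corner name).
#' @param top,bottom Detector-plane (x, y) in mm of the top and bottom
#'   marker projections; must be finite.
#' @return Object of class `marker_pair_observation`.
#' @export
marker_pair_observation <- function(label, top, bottom) {
  top <- as.numeric(top); bottom <- as.numeric(bottom)
  if (length(top) != 2L || length(bottom) != 2L ||
      !all(is.finite(c(top, bottom))))
    stop_radqc("top and bottom must be finite (x, y) pairs",
               class = "radqc_invalid_observation")
  structure(list(label = as.character(label), top = top, bottom = bottom),
            class = "marker_pair_observation")
}

#' Detector-plane line
#'
#' A line `point + s * direction` in the detector plane; the direction is
#' normalized to unit length with a canonical sign (positive x component,
#' tie broken toward positive y) so equal lines compare equal.
#'
#' @param point (x, y) on the line, mm.
#' @param direction Direction vector (any nonzero length).
#' @return Object of class `detector_line`.
#' @export
detector_line <- function(point, direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0)
    stop_radqc("zero direction vector", class = "radqc_invalid_observation")
  d <- direction / nrm
  if (d[1L] < 0 || (d[1L] == 0 && d[2L] < 0)) d <- -d
  structure(list(point = as.numeric(point), direction = d),
            class = "detector_line")
}

#' Line through a marker pair's projections
#'
#' The projections of a vertically aligned marker pair and the
#' perpendicular-ray point are collinear for any point source, so the line
#' through the two projections constrains the perpendicular ray. Pairs whose
#' projections (nearly) coincide sit on the perpendicular ray itself; they
#' are returned as an `on_axis_pair` carrying that shared point instead of
#' a direction.
#'
#' @param obs A [marker_pair_observation()].
#' @param eps_sep Minimum projection separation (mm) below which the pair
#'   is treated as on-axis. Default 0.05 mm.
#' @return A [detector_line()], or an object of class `on_axis_pair` with
#'   element `point`.
#' @export
line_through_pair <- function(obs, eps_sep = 0.05) {
  stopifnot(inherits(obs, "marker_pair_observation"))
  v <- obs$top - obs$bottom
  if (sqrt(sum(v^2)) <= eps_sep)
    return(structure(list(point = (obs$top + obs$bottom) / 2,
                          label = obs$label),
                     class = "on_axis_pair"))
  detector_line(obs$bottom, v)
}

# Signed point-to-line distance in 2D.
point_line_distance <- function(p, line) {
  w <- p - line$point
  abs(w[1L] * line$direction[2L] - w[2L] * line$direction[1L])
}

#' Locate the perpendicular ray from marker-pair lines
#'
#' Estimates the point where the x-ray beam meets the detector
#' perpendicularly, from the lines through projected marker pairs. Two
#' estimators are provided:
#' \describe{
#'   \item{`least_squares` (default)}{The point minimizing the sum of
#'     squared point-to-line distances, solved from the normal equations
#'     \eqn{\sum_i (I - d_i d_i^T)(x - p_i) = 0}.}
#'   \item{`pairwise_centroid`}{Intersects every pair of lines crossing at
#'     more than `theta_min_deg` and returns the centroid of the
#'     intersection points — the manual overlap-points procedure done on a
#'     workstation.}
#' }
#' Both agree exactly on noiseless input; under localization noise the
#' least-squares estimate is the more efficient of the two. A minimum of
#' two non-parallel lines is required; four pairs improve precision. Any
#' `on_axis_pair` in the input short-circuits the estimate: its shared
#' point is (within localization error) the perpendicular ray itself.
#'
#' @param lines List of [detector_line()] (and/or `on_axis_pair`) objects.
#' @param method `"least_squares"` or `"pairwise_centroid"`.
#' @param theta_min_deg Minimum crossing angle (degrees) for a pair of
#'   lines to contribute an intersection point. Default 0.5.
#' @return Object of class `perpendicularity_result` with `perp_ray`
#'   (x, y in mm), `method`, `per_line_residuals` (point-to-line distances,
#'   mm), `intersection_cloud` (matrix, pairwise method only), and an empty
#'   `deviations` slot filled by [deviation_report()].
#' @export
locate_perpendicular_ray <- function(lines,
                                     method = c("least_squares",
                                                "pairwise_centroid"),
                                     theta_min_deg = 0.5) {
  method <- match.arg(method)
  on_axis <- Filter(function(l) inherits(l, "on_axis_pair"), lines)
  proper <- Filter(function(l) inherits(l, "detector_line"), lines)
  if (length(on_axis) > 0) {
    pts <- do.call(rbind, lapply(on_axis, `[[`, "point"))
    est <- colMeans(pts)
    res <- vapply(proper, function(l) point_line_distance(est, l), numeric(1))
    return(new_perp_result(est, "on_axis", res, NULL))
  }
  if (length(proper) < 2L)
    stop_radqc("need at least two marker-pair lines",
               class = "radqc_insufficient_data")

  if (method == "least_squares") {
    A <- matrix(0, 2, 2); b <- c(0, 0)
    for (l in proper) {
      P <- diag(2) - tcrossprod(l$direction)
      A <- A + P
      b <- b + P %*% l$point
    }
    # rank < 2 iff all directions are (anti)parallel
    if (rcond(A) < 1e-10)
      stop_radqc("all marker-pair lines are (near-)parallel: ",
                 "perpendicular ray not identifiable",
                 class = "radqc_degenerate_geometry")
    est <- as.numeric(solve(A, b))
    cloud <- NULL
  } else {
    theta_min <- theta_min_deg * pi / 180
    cloud <- NULL
    n <- length(proper)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      li <- proper[[i]]; lj <- proper[[j]]
      cross <- abs(li$direction[1L] * lj$direction[2L] -
                   li$direction[2L] * lj$direction[1L])
      if (asin(min(cross, 1)) <= theta_min) next
      # solve p_i + s d_i = p_j + u d_j
      M <- cbind(li$direction, -lj$direction)
      su <- solve(M, lj$point - li$point)
      cloud <- rbind(cloud, li$point + su[1L] * li$direction)
    }
    if (is.null(cloud))
      stop_radqc("no line pair crosses at more than the minimum angle",
                 class = "radqc_degenerate_geometry")
    est <- colMeans(cloud)
  }
  res <- vapply(proper, function(l) point_line_distance(est, l), numeric(1))
  new_perp_result(est, method, res, cloud)
}

new_perp_result <- function(perp_ray, method, residuals, cloud) {
  structure(list(perp_ray = perp_ray, method = method,
                 per_line_residuals = residuals,
                 intersection_cloud = cloud,
                 deviations = numeric(0)),
            class = "perpendicularity_result")
}

#' @export
print.perpendicularity_result <- function(x, ...) {
  cat(sprintf("<perpendicularity_result> perp ray at (%.3f, %.3f) mm [%s]\n",
              x$perp_ray[1L], x$perp_ray[2L], x$method))
  if (length(x$per_line_residuals))
    cat("  per-line residuals (mm):",
        paste(sprintf("%.4f", x$per_line_residuals), collapse = ", "), "\n")
  if (length(x$deviations))
    for (nm in names(x$deviations))
      cat(sprintf("  distance to %s: %.3f mm\n", nm, x$deviations[[nm]]))
  invisible(x)
}

#' Fill deviation distances into a perpendicularity result
#'
#' Euclidean distances from the estimated perpendicular ray to each
#' provided reference point: detector center, light-field center (the
#' central top fiducial's projection), and/or central ray. Omitted
#' references are skipped.
#'
#' @param result A `perpendicularity_result`.
#' @param detector_center (x, y) mm.
#' @param light_field_center,central_ray Optional (x, y) mm.
#' @return The result with `deviations` filled (named, mm).
#' @export
deviation_report <- function(result, detector_center,
                             light_field_center = NULL, central_ray = NULL) {
  stopifnot(inherits(result, "perpendicularity_result"))
  dist2 <- function(p) sqrt(sum((result$perp_ray - p)^2))
  dev <- c(detector_center = dist2(detector_center))
  if (!is.null(light_field_center))
    dev <- c(dev, light_field_center = dist2(light_field_center))
  if (!is.null(central_ray))
    dev <- c(dev, central_ray = dist2(central_ray))
  result$deviations <- dev
  result
}

#' Estimate the source-image distance from top-marker magnification
#'
#' The four top markers sit on a square of known side (2 x half width) at
#' known height H above the detector; their projections are magnified by
#' \eqn{m = \mathrm{SID}/(\mathrm{SID} - H)} independently of the source
#' position. Inverting the mean pairwise magnification gives
#' \deqn{\mathrm{SID} = H\,m / (m - 1).}
#' Labels must identify the platform corners (NE/NW/SW/SE) so true pairwise
#' spacings are known.
#'
#' @param observations List of [marker_pair_observation()] with corner
#'   labels, at least 2.
#' @param platform_height Top-marker height H, mm.
#' @param platform_half_width Half the platform side, mm.
#' @return Estimated SID, mm.
#' @export
estimate_sid <- function(observations, platform_height = 200,
                         platform_half_width = 50) {
  hw <- platform_half_width
  corners <- list(NE = c(hw, hw), NW = c(-hw, hw),
                  SW = c(-hw, -hw), SE = c(hw, -hw))
  labs <- vapply(observations, `[[`, character(1), "label")
  if (!all(labs %in% names(corners)))
    stop_radqc("observations must carry corner labels NE/NW/SW/SE",
               class = "radqc_invalid_observation")
  if (length(observations) < 2L)
    stop_radqc("need >= 2 top markers with known spacing",
               class = "radqc_insufficient_data")
  tops <- do.call(rbind, lapply(observations, `[[`, "top"))
  true <- do.call(rbind, corners[labs])
  ratios <- c()
  n <- nrow(tops)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d_true <- sqrt(sum((true[i, ] - true[j, ])^2))
    if (d_true == 0) next
    ratios <- c(ratios, sqrt(sum((tops[i, ] - tops[j, ])^2)) / d_true)
  }
  m <- mean(ratios)
  if (m <= 1 + 1e-6)
    stop_radqc("magnification <= 1: non-physical (parallel-beam limit)",
               class = "radqc_degenerate_geometry")
  platform_height * m / (m - 1)
}
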