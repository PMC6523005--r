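#' One tube voltage's transmission measurement block
#'
#' Container for the repeated air-kerma-rate readings at stepped absorber
#' thicknesses for a single beam quality, together with the aluminum HVL
#' reported by the dosimetry system and (optionally) the per-article areal
#' density used for HVD computation.
#'
#' @param tube_voltage Nominal tube voltage, kV.
#' @param thicknesses Nominal absorber thicknesses, cm; at least 5 distinct
#'   values including 0.
#' @param kerma Matrix of kerma rates (mGy/min), rows = thicknesses,
#'   columns = repeats; all entries must be positive. A vector is accepted
#'   for a single repeat.
#' @param hvl_al_reported Dosimeter-reported aluminum HVL, mm (NA if absent).
#' @param areal_density_per_article Areal density of one absorber article,
#'   g/cm2 (NULL if not measured).
#' @param article_thickness_cm Nominal thickness of one article, cm.
#' @return Object of class `transmission_series`.
#' @export
transmission_series <- function(tube_voltage, thicknesses, kerma,
                                hvl_al_reported = NA_real_,
                                areal_density_per_article = NULL,
                                article_thickness_cm = 0.5) {
  thicknesses <- as.numeric(thicknesses)
  if (is.vector(kerma)) kerma <- matrix(kerma, ncol = 1L)
  if (nrow(kerma) != length(thicknesses))
    stop_radqc("kerma must have one row per thickness",
               class = "radqc_invalid_series")
  if (length(unique(thicknesses)) < 5L || !any(thicknesses == 0))
    stop_radqc("need >= 5 distinct thicknesses including 0",
               class = "radqc_invalid_series")
  if (any(kerma <= 0))
    stop_radqc("all kerma rates must be positive",
               class = "radqc_invalid_series")
  means <- rowMeans(kerma)
  ord <- order(thicknesses)
  if (any(diff(means[ord]) > 0))
    warning("mean kerma rate is not non-increasing in thickness; ",
            "check measurement order or noise level")
  structure(list(tube_voltage = tube_voltage,
                 thicknesses = thicknesses,
                 kerma = kerma,
                 hvl_al_reported = hvl_al_reported,
                 areal_density_per_article = areal_density_per_article,
                 article_thickness_cm = article_thickness_cm),
            class = "transmission_series")
}

#' @export
print.transmission_series <- function(x, ...) {
  cat(sprintf("<transmission_series> %g kV, %d thicknesses x %d repeats, Al HVL %s mm\n",
              x$tube_voltage, length(x$thicknesses), ncol(x$kerma),
              format(x$hvl_al_reported)))
  invisible(x)
}

#' Average repeated readings per thickness
#'
#' Arithmetic mean of the repeat readings at each thickness — the curve the
#' transmission model is fitted to (averaging before fitting, not pooled
#' repeats).
#'
#' @param series A [transmission_series()].
#' @return data.frame with columns `thickness_cm`, `kerma_mGy_min`.
#' @export
average_repeats <- function(series) {
  stopifnot(inherits(series, "transmission_series"))
  if (ncol(series$kerma) < 1L)
    stop_radqc("empty repeat set", class = "radqc_invalid_series")
  data.frame(thickness_cm = series$thicknesses,
             kerma_mGy_min = rowMeans(series$kerma))
}

#' Fit a double-exponential transmission model
#'
#' Fits \deqn{K(t) = a_1 e^{-m_1 t} + a_2 e^{-m_2 t}}
#' to averaged kerma-vs-thickness data by bound-constrained nonlinear least
#' squares (Levenberg-Marquardt via \pkg{minpack.lm}, all four parameters
#' constrained non-negative). This "second-order exponential decay" is the
#' natural form for a polyenergetic beam: preferential absorption of the
#' soft spectral component (beam hardening) makes a single exponential
#' systematically lax.
#'
#' Starting values come from a log-linear single-exponential fit with the
#' rate split by factors 0.5x, 1x and 2x into a fast/slow pair; the
#' best-of-starts solution is returned with the canonical ordering
#' \eqn{m_1 \ge m_2}. The fit is flagged non-converged when the residual
#' RMSE exceeds 5\% of the fitted zero-thickness value. Data with
#' negligible decay return the degenerate \eqn{m_1 = m_2 = 0} fit flagged
#' non-attenuating (downstream HVL solving then errors).
#'
#' @param thickness Thicknesses (cm, or g/cm2 for areal-density fits).
#' @param kerma Mean kerma rate at each thickness; positive.
#' @return Object of class `double_exp_fit` with elements `a1`, `m1`, `a2`,
#'   `m2` (m1 >= m2), `rmse`, `converged`, `attenuating`.
#' @seealso [solve_hvl()], [average_repeats()]
#' @export
fit_double_exponential <- function(thickness, kerma) {
  if (is.data.frame(thickness)) {      # accept average_repeats() output
    kerma <- thickness[[2L]]
    thickness <- thickness[[1L]]
  }
  if (length(thickness) < 5L)
    stop_radqc("need >= 5 points for a 4-parameter fit",
               class = "radqc_invalid_series")
  if (any(kerma <= 0))
    stop_radqc("kerma values must be positive", class = "radqc_invalid_series")
  if (length(kerma) != length(thickness))
    stop_radqc("thickness and kerma lengths differ",
               class = "radqc_invalid_series")

  # degenerate: no measurable decay
  if (diff(range(kerma)) <= 1e-12 * max(kerma)) {
    a <- mean(kerma)
    fit <- new_double_exp_fit(a / 2, 0, a / 2, 0,
                              rmse = sqrt(mean((kerma - a)^2)),
                              converged = TRUE, attenuating = FALSE)
    return(fit)
  }

  # log-linear seed: ln K = ln a0 - m0 t
  seed_fit <- lm(log(kerma) ~ thickness)
  m0 <- max(-coef(seed_fit)[[2L]], 1e-8)
  a0 <- exp(coef(seed_fit)[[1L]])
  residual_fn <- function(p)
    kerma - (p[1L] * exp(-p[2L] * thickness) + p[3L] * exp(-p[4L] * thickness))
  best <- NULL
  for (s in c(0.5, 1, 2)) {
    start <- c(a1 = a0 / 2, m1 = 2 * m0 * s, a2 = a0 / 2, m2 = 0.5 * m0 * s)
    cand <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = residual_fn,
                         lower = c(0, 0, 0, 0),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:4) {
      if (is.null(best) || cand$deviance < best$deviance) best <- cand
    }
  }
  if (is.null(best))
    stop_radqc("no start converged; data are not monotone-dominant decay",
               class = "radqc_fit_failed")
  p <- best$par
  if (p[["m1"]] < p[["m2"]])
    p <- c(a1 = p[["a2"]], m1 = p[["m2"]], a2 = p[["a1"]], m2 = p[["m1"]])
  rmse <- sqrt(best$deviance / length(kerma))
  k0 <- p[["a1"]] + p[["a2"]]
  new_double_exp_fit(p[["a1"]], p[["m1"]], p[["a2"]], p[["m2"]],
                     rmse = rmse,
                     converged = rmse <= 0.05 * k0,
                     attenuating = p[["m1"]] + p[["m2"]] > 0)
}

new_double_exp_fit <- function(a1, m1, a2, m2, rmse, converged, attenuating) {
  structure(list(a1 = a1, m1 = m1, a2 = a2, m2 = m2, rmse = rmse,
                 converged = converged, attenuating = attenuating),
            class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<double_exp_fit> K(t) = %.4g e^(-%.4g t) + %.4g e^(-%.4g t), RMSE %.3g%s\n",
    x$a1, x$m1, x$a2, x$m2, x$rmse,
    if (!x$converged) " [not converged]"
    else if (!x$attenuating) " [non-attenuating]" else ""))
  invisible(x)
}

#' Evaluate a fitted double-exponential curve
#'
#' @param object A `double_exp_fit`.
#' @param thickness Thicknesses at which to evaluate.
#' @param ... Unused.
#' @return Fitted kerma rates.
#' @export
predict.double_exp_fit <- function(object, thickness, ...) {
  object$a1 * exp(-object$m1 * thickness) + object$a2 * exp(-object$m2 * thickness)
}

#' Solve a fitted transmission curve for the half-value layer
#'
#' Finds the thickness at which the fitted curve equals half its reference
#' value by bracketed bisection to |dt| < 1e-9 cm, and returns it in mm.
#' By default the reference is the *fitted* zero-thickness value
#' \eqn{a_1 + a_2}; the measured zero-thickness mean can be supplied
#' instead via `reference = "measured"`. For a single-exponential fit the
#' result equals \eqn{10 \ln 2 / m} mm.
#'
#' @param fit A converged, attenuating `double_exp_fit` (fitted on cm).
#' @param reference `"fitted"` (default) or `"measured"`.
#' @param measured_zero Measured zero-thickness kerma rate, required for
#'   `reference = "measured"`.
#' @return Half-value layer in mm.
#' @export
solve_hvl <- function(fit, reference = c("fitted", "measured"),
                      measured_zero = NULL) {
  stopifnot(inherits(fit, "double_exp_fit"))
  reference <- match.arg(reference)
  k0 <- fit$a1 + fit$a2
  if (!fit$attenuating || k0 <= 0 || fit$m1 + fit$m2 <= 0)
    stop_radqc("fit is non-attenuating; HVL undefined",
               class = "radqc_non_attenuating")
  target <- if (reference == "fitted") k0 / 2 else {
    if (is.null(measured_zero))
      stop_radqc("measured_zero required for reference = 'measured'",
                 class = "radqc_invalid_series")
    measured_zero / 2
  }
  f <- function(t) predict(fit, t) - target
  if (f(0) <= 0)
    stop_radqc("reference level at or above fitted curve at t = 0",
               class = "radqc_no_root")
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e6)
      stop_radqc("no half-value root in bracket; fit barely attenuates",
                 class = "radqc_no_root")
  }
  10 * bisect_root(f, 0, hi, tol = 1e-9)
}

#' Linear attenuation coefficient from a half-value layer
#'
#' \eqn{\mu = \ln 2 / t_{1/2}}, per mm for HVL in mm. (Some write this as
#' ln(0.5)/HVL with the sign absorbed; the coefficient reported here is
#' positive, matching convention.) Vectorized.
#'
#' @param hvl Half-value layer(s), mm; positive.
#' @return Attenuation coefficient(s), per mm.
#' @export
#' @examples
#' signif(compute_mu(20.1), 3)  # 0.0345 / mm
compute_mu <- function(hvl) {
  if (any(hvl <= 0))
    stop_radqc("HVL must be positive", class = "radqc_invalid_series")
  log(2) / hvl
}

#' Half-value density from a transmission series
#'
#' The half-value density (HVD) is the areal density (g/cm2) of absorber
#' that halves the kerma rate — the thickness-free analogue of the HVL,
#' which removes physical-density dependence. The averaged curve is refitted
#' against cumulative areal density (thickness / article thickness x
#' per-article areal density) and solved for 50\% exactly as in
#' [solve_hvl()]. For articles of uniform areal density this equals the
#' nominal scaling `hvl_cm / article_thickness_cm * areal_density`; both
#' paths are computed and must agree within 1e-6 relative.
#'
#' @param series A [transmission_series()] with
#'   `areal_density_per_article` set (or supplied here).
#' @param hvl_mm Fit-derived HVL in mm for the nominal-scaling cross-check;
#'   if NULL it is computed from the series.
#' @param areal_density_per_article Override for the series metadata, g/cm2.
#' @return HVD in g/cm2.
#' @export
compute_hvd <- function(series, hvl_mm = NULL,
                        areal_density_per_article = series$areal_density_per_article) {
  stopifnot(inherits(series, "transmission_series"))
  if (is.null(areal_density_per_article))
    stop_radqc("areal density metadata missing; HVD undefined",
               class = "radqc_missing_metadata")
  avg <- average_repeats(series)
  if (is.null(hvl_mm))
    hvl_mm <- solve_hvl(fit_double_exponential(avg))
  scale <- areal_density_per_article / series$article_thickness_cm  # g/cm2 per cm
  fit_ad <- fit_double_exponential(avg$thickness_cm * scale, avg$kerma_mGy_min)
  hvd <- solve_hvl(fit_ad) / 10        # solve_hvl reports 10x its abscissa unit
  hvd_nominal <- hvl_mm / 10 * scale
  if (abs(hvd - hvd_nominal) > 1e-6 * hvd_nominal)
    warning(sprintf(
      "HVD paths disagree: refit %.8g vs nominal scaling %.8g g/cm2", hvd,
      hvd_nominal))
  hvd
}

#' Quadratic voltage trend of HVL or HVD
#'
#' Unweighted ordinary least squares fit of
#' \deqn{y = a\,\mathrm{kV}^2 + b\,\mathrm{kV} + c} to per-voltage HVL (cm)
#' or HVD (g/cm2) values; exact on data lying on a quadratic.
#'
#' @param kv Tube voltages (>= 3 distinct values).
#' @param y Response values (HVL in cm or HVD in g/cm2).
#' @param y_kind Label recording the response kind.
#' @return Object of class `quadratic_trend` with coefficients `a`, `b`,
#'   `c` and the fitted `lm` in `$model`.
#' @export
fit_quadratic_trend <- function(kv, y, y_kind = c("hvl_cm", "hvd_g_cm2")) {
  y_kind <- match.arg(y_kind)
  if (length(unique(kv)) < 3L)
    stop_radqc("need >= 3 distinct tube voltages", class = "radqc_underdetermined")
  fit <- lm(y ~ kv + I(kv^2))
  structure(list(a = coef(fit)[[3L]], b = coef(fit)[[2L]], c = coef(fit)[[1L]],
                 y_kind = y_kind, model = fit),
            class = "quadratic_trend")
}

#' @export
print.quadratic_trend <- function(x, ...) {
  cat(sprintf("<quadratic_trend> %s = %.3g kV^2 + %.3g kV + %.3g\n",
              x$y_kind, x$a, x$b, x$c))
  invisible(x)
}

#' @export
predict.quadratic_trend <- function(object, kv, ...) {
  object$a * kv^2 + object$b * kv + object$c
}

#' Cross-material HVL line
#'
#' Unweighted OLS of specimen HVL (mm) on aluminum HVL (mm), characterising
#' the specimen's beam-quality response against the standard reference
#' material.
#'
#' @param hvl_al Aluminum HVLs, mm (>= 2 distinct values).
#' @param hvl_specimen Specimen HVLs, mm.
#' @return Object of class `linear_cross_fit` with `slope`, `intercept`
#'   and the fitted `lm` in `$model`.
#' @export
fit_cross_material_line <- function(hvl_al, hvl_specimen) {
  if (length(unique(hvl_al)) < 2L)
    stop_radqc("need >= 2 distinct aluminum HVLs", class = "radqc_underdetermined")
  fit <- lm(hvl_specimen ~ hvl_al)
  structure(list(slope = coef(fit)[[2L]], intercept = coef(fit)[[1L]],
                 model = fit),
            class = "linear_cross_fit")
}

#' @export
print.linear_cross_fit <- function(x, ...) {
  cat(sprintf("<linear_cross_fit> HVL_specimen = %.3g x HVL_Al + %.3g (mm)\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Per-voltage beam-quality table
#'
#' Runs the attenuation chain (average, fit, HVL, optional HVD) for each
#' series and assembles one record per tube voltage with attenuation
#' coefficients for both materials derived via [compute_mu()]. By
#' construction `mu_specimen_per_mm * hvl_specimen_mm = ln 2` for every row.
#'
#' @param series_list List of [transmission_series()].
#' @param fits Optional list of pre-computed `double_exp_fit` objects
#'   matching `series_list`; fitted from the data when NULL.
#' @return data.frame sorted by voltage with columns `tube_voltage_kv`,
#'   `hvl_specimen_mm`, `mu_specimen_per_mm`, `hvl_al_mm`, `mu_al_per_mm`,
#'   `hvd_g_cm2` (NA where areal density is absent), `fit_rmse`.
#' @export
build_beam_quality_table <- function(series_list, fits = NULL) {
  if (length(series_list) == 0L)
    return(data.frame(tube_voltage_kv = numeric(), hvl_specimen_mm = numeric(),
                      mu_specimen_per_mm = numeric(), hvl_al_mm = numeric(),
                      mu_al_per_mm = numeric(), hvd_g_cm2 = numeric(),
                      fit_rmse = numeric()))
  kvs <- vapply(series_list, `[[`, numeric(1), "tube_voltage")
  if (anyDuplicated(kvs))
    stop_radqc("duplicate tube voltage entries", class = "radqc_invalid_series")
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    fit <- if (is.null(fits)) fit_double_exponential(average_repeats(s))
           else fits[[i]]
    if (!fit$converged)
      stop_radqc("fit for ", s$tube_voltage, " kV did not converge",
                 class = "radqc_fit_failed")
    hvl <- solve_hvl(fit)
    hvd <- if (!is.null(s$areal_density_per_article))
      compute_hvd(s, hvl_mm = hvl) else NA_real_
    data.frame(tube_voltage_kv = s$tube_voltage,
               hvl_specimen_mm = hvl,
               mu_specimen_per_mm = compute_mu(hvl),
               hvl_al_mm = s$hvl_al_reported,
               mu_al_per_mm = if (is.na(s$hvl_al_reported)) NA_real_
                              else compute_mu(s$hvl_al_reported),
               hvd_g_cm2 = hvd,
               fit_rmse = fit$rmse)
  })
  out <- do.call(rbind, rows)
  out[order(out$tube_voltage_kv), , drop = FALSE]
}
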