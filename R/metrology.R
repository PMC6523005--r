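#' Validate printed test-article metrology
#'
#' Assembles per-article caliper and scale measurements into a validated
#' table. Dimensions must be strictly positive; lateral dimensions outside
#' 4-6 cm only trigger a protocol-conformance warning (the nominal article
#' is a 5 x 5 x 0.5 cm slab).
#'
#' @param length_cm,width_cm,thickness_cm Per-article dimensions, cm.
#' @param mass_g Per-article mass, g.
#' @return data.frame with the inputs plus `areal_density_g_cm2`.
#' @export
test_articles <- function(length_cm, width_cm, thickness_cm, mass_g) {
  n <- length(mass_g)
  stopifnot(length(length_cm) == n, length(width_cm) == n,
            length(thickness_cm) == n)
  if (any(c(length_cm, width_cm, thickness_cm, mass_g) <= 0))
    stop_radqc("article dimensions and mass must be strictly positive",
               class = "radqc_invalid_article")
  if (any(length_cm < 4 | length_cm > 6 | width_cm < 4 | width_cm > 6))
    warning("lateral dimension outside 4-6 cm: check protocol conformance")
  data.frame(length_cm = length_cm, width_cm = width_cm,
             thickness_cm = thickness_cm, mass_g = mass_g,
             areal_density_g_cm2 = areal_density(mass_g, length_cm, width_cm))
}

#' Areal density of a slab article
#'
#' Mass divided by lateral area: \eqn{\sigma = m / (L \times W)}, g/cm2.
#' Vectorized.
#'
#' @param mass_g Mass, g.
#' @param length_cm,width_cm Lateral dimensions, cm.
#' @return Areal density, g/cm2.
#' @export
#' @examples
#' areal_density(14.75, 5, 5)  # 0.59 g/cm2
areal_density <- function(mass_g, length_cm, width_cm) {
  if (any(mass_g <= 0) || any(length_cm <= 0) || any(width_cm <= 0))
    stop_radqc("mass and dimensions must be strictly positive",
               class = "radqc_invalid_article")
  mass_g / (length_cm * width_cm)
}

#' Validate filament diameter readings
#'
#' @param diameters_mm Micrometer readings, mm (n >= 2); values outside the
#'   1.5-2.0 mm filament range warn.
#' @return The readings, invisibly validated.
#' @export
filament_diameters <- function(diameters_mm) {
  if (length(diameters_mm) < 2L)
    stop_radqc("need >= 2 diameter readings", class = "radqc_invalid_article")
  if (any(diameters_mm <= 0))
    stop_radqc("diameters must be positive", class = "radqc_invalid_article")
  if (any(diameters_mm < 1.5 | diameters_mm > 2.0))
    warning("diameter outside 1.5-2.0 mm: check units or filament spec")
  diameters_mm
}

#' Mean, standard deviation and count
#'
#' Standard "mean +/- 1 standard deviation" summary with the n-1
#' denominator; order-invariant.
#'
#' @param values Numeric vector, n >= 2.
#' @return List with `mean`, `sd`, `n`.
#' @export
summarize_values <- function(values) {
  if (length(values) < 2L)
    stop_radqc("need >= 2 values for a standard deviation",
               class = "radqc_invalid_article")
  list(mean = mean(values), sd = sd(values), n = length(values))
}

#' Welch two-sample comparison
#'
#' Unequal-variance two-sided t comparison of two measurement groups (e.g.
#' filament diameters from two spools, or areal densities of two article
#' sets). Degenerate input — both samples constant and identical — reports
#' statistic 0 and p = 1 with a warning rather than failing.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return List with `statistic` (t), `df` (Welch-Satterthwaite), `p_value`.
#' @export
two_sample_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_radqc("each sample needs n >= 2", class = "radqc_invalid_article")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("both samples constant and identical; p reported as 1")
      return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
    }
    stop_radqc("both samples constant with different means: t undefined",
               class = "radqc_degenerate")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
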