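#' Bundled clear-specimen beam-quality reference table
#'
#' Bench reference measurements for the clear (natural) printed-plastic
#' specimen on a portable fluoroscopic C-arm: for each nominal tube voltage
#' (50-120 kV in 10 kV steps), the measured specimen half-value layer (mm,
#' nominal thickness basis) and the aluminum half-value layer reported by
#' the dosimetry system (mm). These are the calibration targets for
#' [default_spectra()] and the worked-example inputs for the trend and
#' cross-material fits.
#'
#' Only the clear specimen is tabulated per voltage; no per-voltage table
#' was published for the green specimen, so green results cannot be
#' recomputed from bundled data (see the methods vignette).
#'
#' @return A data.frame with columns `tube_voltage_kv`, `hvl_specimen_mm`,
#'   `hvl_al_mm`, plus attribute `areal_density_per_article` (0.590 g/cm2
#'   per 0.5 cm article, the clear-specimen mean areal density) and
#'   `article_thickness_cm` (0.5).
#' @export
#' @examples
#' ref <- reference_beam_quality()
#' compute_mu(ref$hvl_specimen_mm)
reference_beam_quality <- function() {
  path <- system.file("extdata", "clear_specimen_beam_quality.csv",
                      package = "radqc", mustWork = TRUE)
  ref <- utils::read.csv(path)
  attr(ref, "areal_density_per_article") <- 0.590
  attr(ref, "article_thickness_cm") <- 0.5
  ref
}
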