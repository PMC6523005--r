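# Frozen independent-oracle constants, computed with a high-precision
# symbolic evaluator (20 digits) and cross-checked with Brent root finding
# at tol 1e-12 before the implementation was written.
TWO_TERM_TRANSMISSION_ORACLE <- 0.22498221989767056   # 0.5 e^-1 + 0.5 e^-2.5
MIXED_DECAY_HALF_THICKNESS_MM <- 21.228942049720326   # 0.5 e^(-.05t)+0.5 e^(-.02t) = 0.5

# Noiseless transmission series from an explicit spectrum model.
make_noiseless_series <- function(model, kv = 80, thicknesses = seq(0, 5, 0.5),
                                  k0 = 100, repeats = 3, hvl_al = NA_real_,
                                  areal_density = NULL) {
  k <- k0 * spectrum_transmission(model, thicknesses)
  transmission_series(kv, thicknesses,
                      matrix(rep(k, repeats), ncol = repeats),
                      hvl_al_reported = hvl_al,
                      areal_density_per_article = areal_density)
}

# Random non-degenerate two-component spectrum model.
random_two_component <- function() {
  w <- runif(1, 0.2, 0.8)
  mu1 <- runif(1, 0.3, 0.8)
  spectrum_model(c(w, 1 - w), mu_specimen = c(mu1, mu1 * runif(1, 0.2, 0.6)))
}

perp_error <- function(scene, method = "least_squares", lines = NULL) {
  if (is.null(lines)) lines <- lapply(scene$observations, line_through_pair)
  est <- locate_perpendicular_ray(lines, method = method)$perp_ray
  sqrt(sum((est - scene$truth$source_foot)^2))
}
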