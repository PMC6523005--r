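test_that("average_repeats is the arithmetic mean per thickness", {
  s <- transmission_series(80, seq(0, 2, 0.5),
                           matrix(10, nrow = 5, ncol = 3))
  expect_equal(average_repeats(s)$kerma_mGy_min, rep(10, 5))
  s2 <- transmission_series(80, seq(0, 2, 0.5),
                            cbind(rep(9, 5), rep(10, 5), rep(11, 5)))
  expect_equal(average_repeats(s2)$kerma_mGy_min, rep(10, 5))
  # noiseless simulator output averages to the exact model values
  proto <- transmission_protocol(tube_voltages = 70, noise_cv = 0, seed = 2)
  ex <- simulate_transmission_experiment(proto)
  avg <- average_repeats(ex$series[[1]])
  ideal <- proto$kerma_at_zero *
    spectrum_transmission(default_spectra(70)[["70"]], proto$thicknesses)
  expect_identical(avg$kerma_mGy_min, ideal)
})

test_that("series validation catches malformed blocks", {
  expect_error(transmission_series(80, c(0, 1, 2), matrix(1, 3, 2)),
               class = "radqc_invalid_series")
  expect_error(transmission_series(80, seq(0.5, 2.5, 0.5), matrix(1, 5, 2)),
               class = "radqc_invalid_series")
  expect_error(transmission_series(80, seq(0, 2, 0.5),
                                   matrix(c(rep(1, 9), -1), 5, 2)),
               class = "radqc_invalid_series")
  expect_warning(transmission_series(80, seq(0, 2, 0.5),
                                     matrix(c(5, 4, 6, 3, 2), ncol = 1)),
                 "non-increasing")
})

test_that("double-exponential fit nests a single exponential", {
  t <- seq(0, 5, 0.5)
  fit <- fit_double_exponential(t, 100 * exp(-0.3466 * t))
  expect_lt(fit$rmse, 1e-6)
  expect_equal(fit$a1 + fit$a2, 100, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_gte(fit$m1, fit$m2)
})

test_that("double-exponential fit recovers exact two-term parameters", {
  t <- seq(0, 5, 0.5)
  y <- 60 * exp(-0.5 * t) + 40 * exp(-0.2 * t)
  fit <- fit_double_exponential(t, y)
  expect_equal(fit$a1, 60, tolerance = 1e-3)
  expect_equal(fit$m1, 0.5, tolerance = 1e-3)
  expect_equal(fit$a2, 40, tolerance = 1e-3)
  expect_equal(fit$m2, 0.2, tolerance = 1e-3)
})

test_that("constant data yield a flagged non-attenuating fit", {
  fit <- fit_double_exponential(seq(0, 5, 0.5), rep(100, 11))
  expect_false(fit$attenuating)
  expect_identical(c(fit$m1, fit$m2), c(0, 0))
  expect_error(solve_hvl(fit), class = "radqc_non_attenuating")
})

test_that("solve_hvl matches closed form, the bisection oracle, and its defining property", {
  # single-term: HVL = 10 ln2 / m mm
  single <- fit_double_exponential(seq(0, 5, 0.5),
                                   100 * exp(-0.3466 * seq(0, 5, 0.5)))
  expect_equal(solve_hvl(single), 10 * log(2) / 0.3466, tolerance = 1e-6)
  # equal-amplitude mixed decay, rates 0.05 and 0.02 per mm: frozen oracle
  mixed <- radqc:::new_double_exp_fit(50, 0.5, 50, 0.2, rmse = 0,
                                      converged = TRUE, attenuating = TRUE)
  hvl <- solve_hvl(mixed)
  expect_equal(hvl, MIXED_DECAY_HALF_THICKNESS_MM, tolerance = 1e-7)
  # defining property: fitted curve at the HVL equals half the fitted K0
  expect_equal(predict(mixed, hvl / 10), (mixed$a1 + mixed$a2) / 2,
               tolerance = 1e-9)
  # measured-reference variant
  expect_gt(solve_hvl(mixed, reference = "measured", measured_zero = 90),
            hvl)
})

test_that("compute_mu is ln2/HVL, antitone, and matches tabulated values", {
  expect_equal(signif(compute_mu(20.1), 3), 0.0345)
  expect_equal(signif(compute_mu(6.2), 3), 0.112)
  expect_equal(compute_mu(log(2)), 1)
  hvls <- sort(runif(10, 5, 30))
  expect_true(all(diff(compute_mu(hvls)) < 0))
  expect_error(compute_mu(0), class = "radqc_invalid_series")
})

test_that("HVD dual paths agree and reduce to the unit case", {
  # article-thickness HVL: HVD equals one article's areal density
  m_unit <- spectrum_model(1, mu_specimen = log(2) / 0.5)
  s_unit <- make_noiseless_series(m_unit, areal_density = 0.59)
  expect_equal(compute_hvd(s_unit), 0.59, tolerance = 1e-6)
  # dual-path agreement on a hardened beam (refit vs nominal scaling)
  m <- spectrum_model(c(0.5, 0.5), mu_specimen = c(0.6, 0.24))
  s <- make_noiseless_series(m, areal_density = 0.59)
  hvl <- solve_hvl(fit_double_exponential(average_repeats(s)))
  hvd <- expect_silent(compute_hvd(s, hvl_mm = hvl))
  expect_equal(hvd, hvl / 10 / 0.5 * 0.59, tolerance = 1e-6)
  expect_error(compute_hvd(make_noiseless_series(m)),
               class = "radqc_missing_metadata")
})

test_that("quadratic trend is exact on quadratic data and order-invariant", {
  kv <- seq(50, 120, 10)
  y <- 1e-4 * kv^2 - 0.01 * kv + 3
  tr <- fit_quadratic_trend(kv, y)
  expect_equal(c(tr$a, tr$b, tr$c), c(1e-4, -0.01, 3), tolerance = 1e-9)
  # constant response
  trc <- fit_quadratic_trend(c(50, 80, 110), rep(2, 3))
  expect_equal(c(trc$a, trc$b, trc$c), c(0, 0, 2), tolerance = 1e-12)
  # ordering of input points is irrelevant
  o <- sample(length(kv))
  tr2 <- fit_quadratic_trend(kv[o], y[o])
  expect_equal(c(tr2$a, tr2$b, tr2$c), c(tr$a, tr$b, tr$c), tolerance = 1e-12)
  expect_error(fit_quadratic_trend(c(50, 50, 60), 1:3),
               class = "radqc_underdetermined")
})

test_that("cross-material line matches the normal-equation oracle", {
  cf <- fit_cross_material_line(c(2, 4, 6), 2 * c(2, 4, 6) + 15)
  expect_equal(c(cf$slope, cf$intercept), c(2, 15), tolerance = 1e-12)
  set.seed(8)
  x <- runif(12, 2, 7); y <- 1.9 * x + 15 + rnorm(12, 0, 0.3)
  cf2 <- fit_cross_material_line(x, y)
  sxy <- sum((x - mean(x)) * (y - mean(y))); sxx <- sum((x - mean(x))^2)
  expect_equal(cf2$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(cf2$intercept, mean(y) - sxy / sxx * mean(x), tolerance = 1e-12)
  expect_error(fit_cross_material_line(c(3, 3), c(1, 2)),
               class = "radqc_underdetermined")
})

test_that("beam-quality table satisfies mu x HVL = ln2 and tracks ground truth", {
  proto <- transmission_protocol(tube_voltages = c(50, 90, 120),
                                 noise_cv = 0, seed = 3)
  ex <- simulate_transmission_experiment(proto)
  tab <- build_beam_quality_table(ex$series)
  expect_equal(tab$mu_specimen_per_mm * tab$hvl_specimen_mm,
               rep(log(2), 3), tolerance = 1e-9)
  expect_equal(tab$mu_al_per_mm * tab$hvl_al_mm,
               rep(log(2), 3), tolerance = 1e-9)
  expect_equal(tab$tube_voltage_kv, sort(proto$tube_voltages))
  # single-component models: recovery within 0.5% at zero noise
  mus <- c(`50` = 0.345, `90` = 0.28, `120` = 0.257)
  singles <- lapply(mus, function(mu) spectrum_model(1, mu_specimen = mu * 10))
  ex1 <- simulate_transmission_experiment(proto, singles)
  tab1 <- build_beam_quality_table(ex1$series)
  expect_equal(tab1$hvl_specimen_mm, ex1$truth$hvl_true_mm,
               tolerance = 5e-3)
  # structural errors / empty input
  expect_equal(nrow(build_beam_quality_table(list())), 0L)
  expect_error(build_beam_quality_table(list(ex$series[[1]], ex$series[[1]])),
               class = "radqc_invalid_series")
})

test_that("simulate-fit-solve round trip recovers random two-component HVLs", {
  set.seed(99)
  for (i in 1:15) {
    model <- random_two_component()
    s <- make_noiseless_series(model)
    hvl <- solve_hvl(fit_double_exponential(average_repeats(s)))
    truth <- ground_truth_hvl(model, unit = "mm")
    expect_lt(abs(hvl - truth) / truth, 1e-3)
  }
})
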