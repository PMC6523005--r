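test_that("pixel/mm conversion is centered, scaled, and invertible", {
  expect_equal(pixels_to_mm(c(100, 100), 0.2, c(100, 100)), c(0, 0))
  expect_equal(pixels_to_mm(c(110, 95), 0.2, c(100, 100)), c(2, -1))
  p <- matrix(runif(10, -40, 40), ncol = 2)
  expect_equal(pixels_to_mm(mm_to_pixels(p, 0.143, c(512, 512)),
                            0.143, c(512, 512)),
               p, tolerance = 1e-12)
  expect_error(pixels_to_mm(c(1, 1), 0), class = "radqc_invalid_scene")
})

test_that("line through a pair is canonical and detects on-axis pairs", {
  obs <- marker_pair_observation("A", top = c(20, 0), bottom = c(10, 0))
  l <- line_through_pair(obs)
  expect_s3_class(l, "detector_line")
  expect_equal(l$direction, c(1, 0))
  expect_equal(radqc:::point_line_distance(c(10, 0), l), 0)
  # canonical sign: swapping ends gives the same direction
  l2 <- line_through_pair(marker_pair_observation("A", c(10, 0), c(20, 0)))
  expect_equal(l2$direction, l$direction)
  # near-coincident projections signal an on-axis pair
  oa <- line_through_pair(marker_pair_observation("B", c(5, 5),
                                                  c(5.01, 5.01)))
  expect_s3_class(oa, "on_axis_pair")
  expect_equal(oa$point, c(5.005, 5.005))
  expect_error(marker_pair_observation("C", c(1, Inf), c(0, 0)),
               class = "radqc_invalid_observation")
})

test_that("two crossing lines are located exactly by both methods", {
  lines <- list(detector_line(c(3, 0), c(0, 1)),
                detector_line(c(0, -2), c(1, 0)))
  for (m in c("least_squares", "pairwise_centroid")) {
    r <- locate_perpendicular_ray(lines, method = m)
    expect_equal(r$perp_ray, c(3, -2), tolerance = 1e-12)
    expect_true(all(r$per_line_residuals < 1e-12))
  }
  expect_error(locate_perpendicular_ray(lines[1]),
               class = "radqc_insufficient_data")
  parallel <- list(detector_line(c(0, 0), c(1, 0)),
                   detector_line(c(0, 5), c(1, 0)))
  expect_error(locate_perpendicular_ray(parallel),
               class = "radqc_degenerate_geometry")
  expect_error(locate_perpendicular_ray(parallel, method = "pairwise_centroid"),
               class = "radqc_degenerate_geometry")
})

test_that("an on-axis pair pins the perpendicular ray directly", {
  oa <- line_through_pair(marker_pair_observation("B", c(5, 5), c(5, 5)))
  r <- locate_perpendicular_ray(list(oa))
  expect_equal(r$perp_ray, c(5, 5))
  expect_equal(r$method, "on_axis")
})

test_that("noiseless scenes recover the source foot regardless of SID", {
  # randomized configurations (property over seeded draws)
  set.seed(17)
  for (i in 1:100) {
    foot <- runif(2, -40, 40)
    cfg <- scene_config(source_foot = foot, sid = runif(1, 800, 1500),
                        platform_center = runif(2, -30, 30),
                        seed = i)
    sc <- simulate_scene(cfg)
    lines <- lapply(sc$observations, line_through_pair)
    for (m in c("least_squares", "pairwise_centroid")) {
      est <- locate_perpendicular_ray(lines, method = m)$perp_ray
      expect_lt(sqrt(sum((est - foot)^2)), 1e-9)
    }
  }
  # SID sweep with everything else fixed
  ests <- sapply(seq(800, 1500, by = 100), function(sid) {
    sc <- simulate_scene(scene_config(source_foot = c(12.3, -4.5), sid = sid,
                                      platform_center = c(8, 3)))
    locate_perpendicular_ray(lapply(sc$observations,
                                    line_through_pair))$perp_ray
  })
  expect_lt(max(abs(ests - c(12.3, -4.5))), 1e-9)
})

test_that("least squares beats pairwise centroid and gains from more pairs", {
  err <- t(sapply(1:100, function(r) {
    sc <- simulate_scene(scene_config(source_foot = c(8, -6), sid = 1100,
                                      localization_noise_sd = 0.3, seed = r))
    lines <- lapply(sc$observations, line_through_pair)
    c(ls4 = perp_error(sc, lines = lines),
      ctr = perp_error(sc, method = "pairwise_centroid", lines = lines),
      ls2 = sqrt(sum((locate_perpendicular_ray(lines[1:2])$perp_ray -
                        c(8, -6))^2)))
  }))
  expect_lte(median(err[, "ls4"]), median(err[, "ctr"]))
  expect_lt(median(err[, "ls4"]), median(err[, "ls2"]))
})

test_that("deviation distances are Euclidean and translation-invariant", {
  r <- locate_perpendicular_ray(list(detector_line(c(3, 0), c(0, 1)),
                                     detector_line(c(0, 4), c(1, 0))))
  r0 <- deviation_report(r, detector_center = c(3, 4))
  expect_equal(unname(r0$deviations["detector_center"]), 0)
  r1 <- deviation_report(r, detector_center = c(0, 0),
                         light_field_center = c(3, 0))
  expect_equal(unname(r1$deviations["detector_center"]), 5)
  expect_equal(unname(r1$deviations["light_field_center"]), 4)
  # rigid translation of every input leaves distances unchanged
  d <- c(-7, 11)
  rt <- locate_perpendicular_ray(list(detector_line(c(3, 0) + d, c(0, 1)),
                                      detector_line(c(0, 4) + d, c(1, 0))))
  rt <- deviation_report(rt, detector_center = d,
                         light_field_center = c(3, 0) + d)
  expect_equal(rt$deviations, r1$deviations, tolerance = 1e-12)
})

test_that("SID is recovered from top-marker magnification", {
  sc <- simulate_scene(scene_config(source_foot = c(10, 5), sid = 1000))
  expect_equal(estimate_sid(sc$observations), 1000, tolerance = 1e-6)
  # doubling the assumed platform height doubles the estimate
  expect_equal(estimate_sid(sc$observations, platform_height = 400),
               2 * estimate_sid(sc$observations), tolerance = 1e-9)
  # parallel-beam degenerate: unit magnification
  flat <- lapply(list(c(50, 50), c(-50, 50)), function(xy)
    marker_pair_observation(if (xy[1] > 0) "NE" else "NW",
                            top = xy, bottom = xy * 0.99))
  expect_error(estimate_sid(flat), class = "radqc_degenerate_geometry")
})
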