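gaussian_trace <- function(mu = 50, sigma = 0.1, apex = 1000,
                           step = 0.01, from = 48, to = 52) {
  t <- seq(from, to, by = step)
  list(times = t, intensities = apex * exp(-(t - mu)^2 / (2 * sigma^2)))
}

test_that("trapezoidal integration recovers closed-form areas", {
  t <- seq(0, 2, by = 0.001)
  tri <- ifelse(abs(t - 1) <= 0.5, 1000 * (1 - 2 * abs(t - 1)), 0)
  res <- integrate_peak(t, tri, c(0.4, 1.6))
  expect_equal(res$area, 500, tolerance = 1e-3)
  expect_equal(res$apex_height, 1000, tolerance = 1e-6)
  zero <- integrate_peak(t, rep(0, length(t)), c(0.4, 1.6))
  expect_equal(zero$area, 0)
  expect_equal(zero$apex_height, 0)
  expect_error(integrate_peak(t, tri, c(-1, 1)), "outside")
})

test_that("refining the sampling grid changes a Gaussian area by < 0.5%", {
  g1 <- gaussian_trace(step = 0.05)
  g2 <- gaussian_trace(step = 0.025)
  a1 <- integrate_peak(g1$times, g1$intensities, c(49.5, 50.5))$area
  a2 <- integrate_peak(g2$times, g2$intensities, c(49.5, 50.5))$area
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("heavy-defined boundaries bracket the analytic FWHM window", {
  g <- gaussian_trace(step = 0.01)
  b <- pick_boundaries(g$times, list(g$intensities), k = 1.5)
  # FWHM = 2.3548 * 0.1 -> apex +/- 0.3532, within one 0.01-min step
  expect_equal(b[1], 50 - 1.5 * 2.3548 * 0.1, tolerance = 0.011)
  expect_equal(b[2], 50 + 1.5 * 2.3548 * 0.1, tolerance = 0.011)
  # two co-eluting heavy transitions share the apex of either alone
  b2 <- pick_boundaries(g$times, list(g$intensities, 0.5 * g$intensities))
  expect_equal(b2, b, tolerance = 1e-9)
  expect_error(pick_boundaries(g$times, list(rep(0, length(g$times)))),
               "internal standard not detected")
  expect_warning(bf <- pick_boundaries(g$times, list(rep(5, length(g$times)))),
                 "flat")
  expect_equal(bf, range(g$times))
})

test_that("interfered transitions are excluded from reporting", {
  areas <- data.frame(transition = c("y4", "y5", "y6"),
                      heavy_area = c(1000, 800, 600),
                      light_area = c(500, 400, 300))
  clean <- select_reporting_transition(areas)
  expect_identical(clean$transition, "y4")  # proportional: largest heavy
  expect_false(any(clean$interference))
  # inflate y4's light 5-fold: its light fraction deviates > 0.2
  areas$light_area[1] <- 2500
  hit <- select_reporting_transition(areas)
  expect_true(hit$interference[["y4"]])
  expect_false(hit$transition == "y4")
  expect_warning(single <- select_reporting_transition(areas[1, ]), "single")
  expect_identical(single$transition, "y4")
})

test_that("detection categories follow the route-specific height thresholds", {
  r1 <- detect_endogenous(c(10, 10, 10), 260, "pY")
  expect_true(r1$detected); expect_identical(r1$category, 1L)
  r2 <- detect_endogenous(c(10, 10, 10), 260, "IMAC")
  expect_false(r2$detected); expect_identical(r2$category, 2L)
  r3 <- detect_endogenous(c(10, 0, 10), 5000, "IMAC")
  expect_identical(r3$category, 3L)
  expect_error(detect_endogenous(c(1, 1), 100, "TIO"), "unknown")
})

test_that("PAR arithmetic and %CV behave as defined", {
  expect_equal(compute_par(500, 1000), 0.5)
  expect_equal(compute_par(0, 1000), 0)
  expect_error(compute_par(500, 0), "heavy")
  expect_equal(percent_cv(c(1, 1, 1)), 0)
  expect_equal(percent_cv(c(8, 10, 12)), 20)
  expect_equal(percent_cv(3 * c(8, 10, 12)), 20)  # scale invariance
  expect_error(percent_cv(5), "2 values")
})

test_that("PAR is invariant to a common gain on both labels", {
  des <- simulation_design(seed = 3, noise_sd_frac = 0)
  sim <- simulate_chromatograms("pep1", c(pep1 = 0.7), des)
  q1 <- quantify_chromatograms(sim$chromatograms, "IMAC")
  scaled <- sim$chromatograms
  scaled$intensity <- scaled$intensity * 3.7
  q2 <- quantify_chromatograms(scaled, "IMAC")
  expect_equal(q1$par, q2$par, tolerance = 1e-12)
})

test_that("noise-free quantification recovers the simulated truth exactly", {
  des <- simulation_design(seed = 19, noise_sd_frac = 0)
  ratios <- c(a = 0.05, b = 0.5, c = 1, d = 2, e = 5)
  sim <- simulate_chromatograms(names(ratios), ratios, des)
  q <- quantify_chromatograms(sim$chromatograms, "IMAC")
  q <- q[match(names(ratios), q$peptide), ]
  expect_true(all(abs(q$par - ratios) / ratios < 0.01))
})

test_that("category assignment partitions every peptide-sample cell", {
  des <- simulation_design(seed = 4)
  ratios <- c(hi = 1, lo = 0.02, none = 0.0001)
  sim <- simulate_chromatograms(names(ratios), ratios, des)
  q <- quantify_chromatograms(sim$chromatograms, "IMAC")
  expect_identical(nrow(q), 3L)
  expect_true(all(q$category %in% 1:3))
  expect_identical(q$category[q$peptide == "hi"], 1L)
  expect_identical(q$category[q$peptide == "none"], 3L)
})
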