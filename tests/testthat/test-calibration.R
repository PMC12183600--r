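test_that("noise-free points fit exactly, through origin and with intercept", {
  pts <- data.frame(concentration = c(0.1, 0.5, 1, 2.5, 5))
  pts$area <- 167894 * pts$concentration
  crv <- fit_calibration(pts, analyte = "OA", wavelength = 205)
  expect_equal(crv$slope, 167894)
  expect_equal(crv$slope_sd, 0)
  expect_equal(crv$r_squared, 1)
  expect_equal(crv$intercept, 0)
  pts2 <- data.frame(concentration = c(0, 1, 2, 3), area = 10 * (0:3) + 5)
  crv2 <- fit_calibration(pts2, through_origin = FALSE)
  expect_equal(crv2$slope, 10)
  expect_equal(crv2$intercept, 5)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration(data.frame(concentration = c(1, 1, 1),
                                          area = c(1, 2, 3))), "distinct")
  expect_error(fit_calibration(data.frame(concentration = c(-1, 1),
                                          area = c(1, 2))), "negative")
  expect_error(fit_calibration(data.frame(concentration = c(0, 1),
                                          area = c(-1, 2))), "negative")
})

test_that("LOD and LOQ follow 3.3 and 10 sigma over slope", {
  crv <- manual_curve(slope = 167894, sigma = 1570)
  expect_equal(round(crv$lod, 3), 0.031)
  expect_equal(round(crv$loq, 3), 0.094)
  expect_equal(manual_curve(1000, 10)$lod, 0.033)
  expect_equal(manual_curve(1000, 0)$lod, 0)
  expect_equal(manual_curve(1000, 0)$loq, 0)
  bad <- manual_curve(1000, 1)
  bad$sigma <- NA_real_
  expect_error(compute_lod(bad), "sigma_mode")
})

test_that("the LOQ to LOD ratio is exactly 10/3.3 for any curve", {
  for (s in c(30.6, 6309, 167894)) {
    for (sg in c(0.6, 128, 1570)) {
      crv <- manual_curve(s, sg)
      expect_equal(crv$loq / crv$lod, 10 / 3.3, tolerance = 1e-12)
    }
  }
})

test_that("both response-sigma conventions are available and recorded", {
  pts <- data.frame(concentration = rep(c(0.5, 2.5, 5), each = 2))
  pts$area <- 100 * pts$concentration + c(-1, 1, -2, 2, -1, 1)
  a <- fit_calibration(pts, sigma_mode = "slope_sd")
  b <- fit_calibration(pts, sigma_mode = "residual_sd")
  expect_equal(a$sigma, a$slope_sd)
  expect_gt(b$sigma, a$sigma)
  expect_equal(a$sigma_mode, "slope_sd")
  expect_equal(b$sigma_mode, "residual_sd")
})

test_that("repeatability and recovery follow their definitions", {
  pr <- repeatability(c(2.4, 2.5, 2.6))
  expect_equal(pr$mean, 2.5)
  expect_equal(pr$sd, 0.1)
  expect_equal(pr$rsd, 4.0)
  expect_equal(repeatability(c(1, 1, 1))$rsd, 0)
  expect_error(repeatability(c(2.5)), "replicates")
  expect_error(repeatability(c(-1, 1)), "undefined")
  expect_equal(recovery(c(2.5, 2.5), 2.5)$recovery, 100)
  expect_equal(recovery(c(2.2, 2.3), 2.5)$recovery, 90)
  expect_error(recovery(c(1), 0), "> 0")
})

test_that("quantification inverts the line and flags low or clipped results", {
  crv <- manual_curve(167894, 1570, analyte = "OA", wavelength = 205)
  expect_equal(as.numeric(quantify(167894, crv)), 1)
  expect_equal(as.numeric(quantify(0, crv)), 0)
  low <- quantify(167894 * 0.05, crv)
  expect_equal(as.numeric(low), 0.05)
  expect_true(attr(low, "below_loq"))
  neg <- quantify(-10, crv)
  expect_equal(as.numeric(neg), 0)
  expect_true(attr(neg, "clipped"))
  withb <- fit_calibration(data.frame(concentration = 0:3,
                                      area = 10 * (0:3) + 5),
                           through_origin = FALSE)
  expect_equal(as.numeric(quantify(25, withb)), 2)
})

test_that("quantifying fitted noise-free points recovers the levels exactly", {
  pts <- data.frame(concentration = c(0.1, 0.5, 1, 2.5, 5))
  pts$area <- 9994 * pts$concentration
  crv <- fit_calibration(pts)
  expect_equal(as.numeric(quantify(pts$area, crv)), pts$concentration,
               tolerance = 1e-12)
})

test_that("the simulated oxalic calibration is accurate and precise", {
  cal <- calibrate_simulated("OA", 205, noise = noise_model(seed = 7))
  expect_lt(abs(cal$curve$slope - 167894) / 167894, 0.02)
  expect_gt(cal$curve$r_squared, 0.998)
})

test_that("the slope estimator is unbiased over repeated simulations", {
  lib <- default_library()
  grid <- c(11, 14, 0.01)
  levels <- c(0.1, 0.5, 1, 2.5, 5)
  slopes <- vapply(1:50, function(run) {
    areas <- vapply(seq_along(levels), function(li) {
      ch <- simulate_injection(
        c(OA = levels[li]), lib,
        noise_model(seed = derive_seed(20, "bias", run, li)), grid = grid)
      integrate_peak(ch, 205, c(12.37 - 0.6, 12.37 + 0.6))
    }, numeric(1))
    fit_calibration(data.frame(concentration = levels, area = areas))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) / 167894 - 1), 0.005)
})

test_that("simulated repeatability stays inside the validated RSD band", {
  crv <- true_curve("DHA", 205)
  out <- precision_recovery_study("DHA", crv, noise = noise_model(seed = 31))
  rsd <- vapply(out$precision, `[[`, numeric(1), "rsd")
  expect_true(all(rsd < 5))
  rec <- vapply(out$recovery, `[[`, numeric(1), "recovery")
  expect_true(all(rec > 70 & rec < 120))
})
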