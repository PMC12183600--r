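test_that("the baseline reproduces flat offsets and linear drift", {
  t <- seq(0, 30, 0.01)
  flat <- chromatogram(t, list(`205` = rep(0.5, length(t))))
  expect_equal(estimate_baseline(flat, 205), rep(0.5, length(t)),
               tolerance = 1e-12)
  drift <- 0.012 * t
  chd <- chromatogram(t, list(`205` = drift))
  expect_lt(max(abs(estimate_baseline(chd, 205) - drift)), 0.02)
  expect_error(estimate_baseline(flat, 300), "300")
  expect_error(estimate_baseline(flat, 205, window = 0), "window")
})

test_that("the baseline stays near zero under an isolated peak", {
  ch <- simulate_injection(c(OA = 1), noise = noise_free())
  b <- estimate_baseline(ch, 205)
  under <- abs(ch$times - 12.37) < 0.6
  expect_lt(max(abs(b[under])), 0.01 * max(chrom_trace(ch, 205)))
})

test_that("a noise-free 8-analyte standard yields 7 peaks (merged pair)", {
  ch <- simulate_injection(standard_sample(), noise = noise_free())
  p <- detect_peaks(ch, 205)
  expect_equal(nrow(p), 7L)
  expect_equal(p$apex_time, c(12.37, 13.64, 17.13, 18.31, 19.46, 20.76, 22.46),
               tolerance = 1e-6)
  flat <- chromatogram(seq(0, 30, 0.01), list(`205` = numeric(3001)))
  expect_equal(nrow(detect_peaks(flat, 205)), 0L)
  expect_error(detect_peaks(ch, 205, min_height = -1), ">= 0")
})

test_that("trapezoidal integration matches the closed-form Gaussian area", {
  ch <- simulate_injection(c(DHA = 2), noise = noise_free())
  truth <- 17903 * 2
  a5 <- integrate_peak(ch, 205, 20.76 + c(-0.6, 0.6))
  expect_lt(abs(a5 - truth) / truth, 1e-6)
  a1 <- integrate_peak(ch, 205, 20.76 + c(-0.12, 0.12))
  frac <- pracma::erf(1 / sqrt(2))
  expect_equal(a1 / truth, frac, tolerance = 5e-4)  # O(dt^2/sigma^2) grid error
  expect_equal(integrate_peak(chromatogram(seq(0, 1, 0.01),
                                           list(`205` = numeric(101))),
                              205, c(0.2, 0.8)), 0)
  expect_error(integrate_peak(ch, 205, c(21, 20)), "left < right")
  expect_error(integrate_peak(ch, 205, c(-1, 20)), "grid")
})

test_that("integration error falls at second order in the grid step", {
  err <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    ch <- simulate_injection(c(OA = 1), noise = noise_free(),
                             grid = c(0, 30, dt))
    # off-centre bounds so the discretisation error is not symmetric-cancelled
    abs(integrate_peak(ch, 205, c(12.37 - 5 * 0.12, 12.37 + 0.155)) -
          167894 * (pracma::erf(0.155 / 0.12 / sqrt(2)) +
                    pracma::erf(5 / sqrt(2))) / 2)
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)
  expect_lt(err[3], err[2] / 2)
})

test_that("peaks are assigned by retention time with co-elution groups", {
  lib <- default_library()
  p <- assign_peaks(make_peaks(c(12.40, 19.46, 11.38)), lib)
  expect_equal(p$assigned[p$apex_time == 12.40], "OA")
  merged <- p[p$apex_time == 19.46, ]
  expect_setequal(merged$coelution_group[[1]], c("FA", "GlyAld"))
  expect_true(is.na(p$assigned[p$apex_time == 11.38]))
  expect_error(assign_peaks(make_peaks(12.4), lib, tolerance = 0), "> 0")
})

test_that("two peaks competing for one analyte are flagged ambiguous", {
  lib <- default_library()
  expect_warning(p <- assign_peaks(make_peaks(c(12.30, 12.45)), lib), "OA")
  expect_true(all(p$ambiguous))
  expect_equal(p$assigned, c("OA", "OA"))
})

test_that("resolution follows Rs = 2 dt / (w1 + w2) and its invariances", {
  rs_lg <- resolution(peak_shape(17.88, 0.12), peak_shape(18.33, 0.12))
  expect_equal(rs_lg, 2 * 0.45 / (0.96), tolerance = 1e-12)
  expect_lt(rs_lg, 1.5)
  rs_ga <- resolution(peak_shape(17.13, 0.12), peak_shape(18.31, 0.12))
  expect_equal(rs_ga, 2 * 1.18 / 0.96, tolerance = 1e-12)
  expect_gt(rs_ga, 1.5)
  expect_equal(resolution(peak_shape(10, 0.1), peak_shape(10, 0.1)), 0)
  # translation invariance and monotonicity in separation
  for (shift in c(-3, 2, 7.5)) {
    expect_equal(resolution(peak_shape(17.88 + shift, 0.12),
                            peak_shape(18.33 + shift, 0.12)), rs_lg)
  }
  seps <- seq(0.1, 2, by = 0.1)
  rs <- vapply(seps, function(d)
    resolution(peak_shape(15, 0.12), peak_shape(15 + d, 0.12)), numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("the two-Gaussian fit recovers overlapped component areas", {
  lib <- default_library(extras = "lactic")
  ch <- simulate_injection(c(lactic = 1, GCA = 1), lib, noise_free())
  f <- fit_overlapped_pair(ch, 205, c(17.3, 18.9), init = c(17.88, 18.31))
  expect_true(f$converged)
  areas <- f$components$area[order(f$components$center)]
  expect_lt(abs(areas[1] - 8000) / 8000, 0.02)
  expect_lt(abs(areas[2] - 7441) / 7441, 0.02)
  # swapped initial centres give the same areas up to relabelling
  f2 <- fit_overlapped_pair(ch, 205, c(17.3, 18.9), init = c(18.31, 17.88))
  expect_equal(sort(f2$components$area), sort(f$components$area),
               tolerance = 1e-4)
})

test_that("a single peak degenerates to one component plus a null one", {
  ch <- simulate_injection(c(GCA = 1), noise = noise_free())
  f <- fit_overlapped_pair(ch, 205, c(17.3, 18.9), init = c(17.7, 18.31))
  areas <- sort(f$components$area)
  expect_lt(areas[1], 0.02 * 7441)
  expect_equal(areas[2], 7441, tolerance = 0.02 * 7441)
  expect_error(fit_overlapped_pair(ch, 205, c(18.9, 17.3), c(17.7, 18.3)),
               "left < right")
  expect_error(fit_overlapped_pair(ch, 205, c(17.3, 18.9), c(10, 18.3)),
               "centres")
})

test_that("simulate-detect-integrate-assign round trip recovers all areas", {
  lib <- default_library()
  sample <- standard_sample()
  ch <- simulate_injection(sample, lib, noise_free())
  p <- assign_peaks(detect_peaks(ch, 205), lib)
  for (an in setdiff(names(sample), c("FA", "GlyAld"))) {
    truth <- response_slope(lib, an, 205) * sample[[an]]
    expect_lt(abs(analyte_area(p, an) - truth) / truth, 0.005)
  }
  merged_truth <- (6309 + 12566)
  expect_lt(abs(analyte_area(p, "FA") - merged_truth) / merged_truth, 0.005)
  # additivity: merged area equals the sum of separately simulated components
  a_fa <- integrate_peak(simulate_injection(c(FA = 1), lib, noise_free()),
                         205, c(18.9, 20.1))
  a_gly <- integrate_peak(simulate_injection(c(GlyAld = 1), lib, noise_free()),
                          205, c(18.9, 20.1))
  expect_equal(analyte_area(p, "FA"), a_fa + a_gly, tolerance = 1e-4)
})
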