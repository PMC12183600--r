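test_that("default library carries the validated retention map and slopes", {
  lib <- default_library()
  expect_setequal(lib$analyte,
                  c("OA", "TA", "GA", "GCA", "FA", "GlyAld", "DHA", "glycerol"))
  expect_equal(lib$retention_time[lib$analyte == "OA"], 12.37)
  expect_equal(response_slope(lib, "OA", 205), 167894)
  expect_equal(lib$retention_time[lib$analyte == "FA"],
               lib$retention_time[lib$analyte == "GlyAld"])
  expect_equal(lib$retention_time[lib$analyte == "FA"], 19.46)
  expect_equal(response_slope(lib, "glycerol", 205), 30.6)
  extended <- default_library(extras = c("lactic", "salt"))
  expect_equal(extended$retention_time[extended$analyte == "lactic"], 17.88)
  expect_equal(extended$retention_time[extended$analyte == "salt"], 11.38)
})

test_that("library overrides pass through and bad keys are rejected by name", {
  lib <- default_library(list(GA = list(retention_time = 17.00)))
  expect_equal(lib$retention_time[lib$analyte == "GA"], 17.00)
  ref <- default_library()
  same <- lib$analyte != "GA"
  expect_equal(lib$retention_time[same], ref$retention_time[same])
  expect_error(default_library(list(XX = list(retention_time = 1))), "XX")
  expect_error(default_library(list(GA = list(bogus = 1))), "bogus")
})

test_that("a noise-free isolated peak integrates to slope times concentration", {
  lib <- default_library()
  ch <- simulate_injection(c(OA = 1), lib, noise_free())
  a <- integrate_peak(ch, 205, c(12.37 - 0.6, 12.37 + 0.6))
  expect_lt(abs(a - 167894), 0.2)
  expect_lt(abs(a - 167894) / 167894, 1e-6)
})

test_that("an empty noise-free sample is identically zero", {
  ch <- simulate_injection(numeric(0), noise = noise_free())
  expect_true(all(chrom_trace(ch, 205) == 0))
  expect_true(all(chrom_trace(ch, 300) == 0))
})

test_that("co-located peaks add: the merged FA/GlyAld area is the slope sum", {
  ch <- simulate_injection(c(FA = 1, GlyAld = 1), noise = noise_free())
  p <- detect_peaks(ch, 205)
  expect_equal(nrow(p), 1L)
  expect_equal(p$apex_time, 19.46, tolerance = 1e-8)
  expect_equal(p$area, 6309 + 12566, tolerance = 1e-4)
})

test_that("identical seeds give bit-identical chromatograms", {
  nz <- noise_model(seed = 99)
  a <- simulate_injection(c(OA = 1), noise = nz)
  b <- simulate_injection(c(OA = 1), noise = nz)
  expect_identical(a$traces, b$traces)
  s1 <- simulate_calibration_series("OA", c(1), 1, noise = noise_model(seed = 4))
  s2 <- simulate_calibration_series("OA", c(1), 1, noise = noise_model(seed = 4))
  expect_identical(s1[[1]]$traces, s2[[1]]$traces)
  s3 <- simulate_calibration_series("OA", c(1), 1, noise = noise_model(seed = 5))
  expect_false(identical(s1[[1]]$traces, s3[[1]]$traces))
})

test_that("noise-free areas are linear in concentration", {
  lib <- default_library()
  a1 <- integrate_peak(simulate_injection(c(GA = 1.3), lib, noise_free()),
                       205, c(16.5, 17.8))
  a2 <- integrate_peak(simulate_injection(c(GA = 2.6), lib, noise_free()),
                       205, c(16.5, 17.8))
  expect_lt(abs(a2 / a1 - 2), 1e-9)
})

test_that("simulator validates its inputs", {
  expect_error(simulate_injection(c(nope = 1), noise = noise_free()), "nope")
  expect_error(simulate_injection(c(OA = -1), noise = noise_free()), ">= 0")
  expect_error(simulate_injection(c(OA = 1), noise = noise_free(),
                                  grid = c(12, 30, 0.01)), "5 sigma")
  expect_warning(simulate_injection(c(OA = 1), noise = noise_free(),
                                    grid = c(0, 30, 0.05)), "coarse")
})

test_that("a calibration series has one chromatogram per level and replicate", {
  series <- simulate_calibration_series("OA", c(0.1, 0.5, 1, 2.5, 5), 3,
                                        noise = noise_model(seed = 1))
  expect_length(series, 15L)
  expect_equal(sort(unique(vapply(series, function(ch)
    ch$meta$known_concentration, 0))), c(0.1, 0.5, 1, 2.5, 5))
  expect_warning(
    simulate_calibration_series("OA", c(10), 1, noise = noise_free()),
    "linear range")
  expect_silent(
    simulate_calibration_series("glycerol", c(16, 28, 40), 1,
                                noise = noise_free()))
})

test_that("electrolysis samples carry the quench dilution and the salt peak", {
  lib <- default_library()
  ch <- simulate_electrolysis_sample(c(FA = 10), "alkaline", lib, noise_free())
  expect_equal(ch$meta$dilution_factor, 1.25)
  expect_equal(ch$meta$matrix, "alkaline")
  a_fa <- integrate_peak(ch, 205, c(18.9, 20.1))
  expect_equal(a_fa, 6309 * 10 / 1.25, tolerance = 1e-5)
  a_salt <- integrate_peak(ch, 205, c(10.8, 12.0))
  expect_gt(a_salt, 0)
  # salt sits > 0.9 min from the nearest analyte peak (OA)
  expect_gt(12.37 - 11.38, 0.9)
  flat <- simulate_electrolysis_sample(stats::setNames(numeric(0), character(0)),
                                       "acidic", lib, noise_free())
  expect_true(all(chrom_trace(flat, 205) == 0))
  expect_error(simulate_electrolysis_sample(c(FA = 1), "neutral", lib,
                                            noise_free()))
})

test_that("only the lactic/glycolic pair falls below baseline resolution", {
  lib <- default_library(extras = "lactic")
  lib <- lib[order(lib$retention_time), ]
  rs <- vapply(seq_len(nrow(lib) - 1), function(i) {
    resolution(peak_shape(lib$retention_time[i], lib$peak_sigma[i]),
               peak_shape(lib$retention_time[i + 1], lib$peak_sigma[i + 1]))
  }, numeric(1))
  pair <- paste(lib$analyte[-nrow(lib)], lib$analyte[-1], sep = "/")
  under <- rs < 1.5 & rs > 0
  expect_equal(pair[under], "lactic/GCA")
  expect_true(all(rs[pair %in% c("FA/GlyAld", "GlyAld/FA")] == 0))
  expect_true(all(rs[!under & rs > 0] > 1.5))
})

test_that("the EMG peak shape option preserves unit area", {
  t <- seq(0, 30, 0.005)
  for (tau in c(0.03, 0.1)) {
    d <- georquant:::peak_density(t, 15, 0.12, shape = "emg", tau = tau)
    expect_equal(pracma::trapz(t, d), 1, tolerance = 1e-6)
  }
  ch <- simulate_injection(c(OA = 1), noise = noise_free(), shape = "emg")
  expect_equal(integrate_peak(ch, 205, c(11.5, 13.8)), 167894,
               tolerance = 1e-4)
})
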