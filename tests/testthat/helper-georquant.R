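# Shared fixtures: everything is generated in code at test time.

# Calibration curve holding the generator's true response slope, for tests
# that isolate downstream arithmetic from calibration-fit noise.
true_curve <- function(analyte, wavelength, lib = default_library(),
                       sigma = 0) {
  slope <- response_slope(lib, analyte, wavelength)
  curve <- structure(list(analyte = analyte, wavelength = wavelength,
                          slope = slope, slope_sd = sigma, intercept = 0,
                          r_squared = 1, sigma = sigma,
                          sigma_mode = "slope_sd", lod = NA_real_,
                          loq = NA_real_, n_points = NA_integer_,
                          through_origin = TRUE),
                     class = "calibration_curve")
  curve$lod <- compute_lod(curve)
  curve$loq <- compute_loq(curve)
  curve
}

true_curve_set <- function(lib = default_library()) {
  keys <- list(c("OA", 205), c("TA", 205), c("GA", 205), c("GCA", 205),
               c("FA", 205), c("GlyAld", 205), c("DHA", 205),
               c("GlyAld", 300))
  out <- list()
  for (k in keys)
    out[[paste0(k[1], "@", k[2])]] <- true_curve(k[1], as.numeric(k[2]), lib)
  out
}

# An 8-analyte standard at the middle calibration level (glycerol at the low
# end of its own range).
standard_sample <- function(conc = 1, glycerol = 20) {
  stats::setNames(c(rep(conc, 7), glycerol),
                  c("OA", "TA", "GA", "GCA", "FA", "GlyAld", "DHA", "glycerol"))
}

# Minimal hand-built peak table for assignment tests.
make_peaks <- function(apex_times, wavelength = 205) {
  out <- data.frame(injection_id = "manual", apex_time = apex_times,
                    left_bound = apex_times - 0.5,
                    right_bound = apex_times + 0.5,
                    height = 1, area = 1, wavelength = wavelength,
                    sigma_est = 0.12, assigned = NA_character_,
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  out$coelution_group <- replicate(nrow(out), character(0), simplify = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}
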