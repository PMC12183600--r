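#' Detect and assign peaks in one trace
#'
#' Convenience wrapper chaining [estimate_baseline()], [detect_peaks()] and
#' [assign_peaks()].
#'
#' @inheritParams detect_peaks
#' @inheritParams assign_peaks
#' @param library Compound library for assignment.
#' @return An assigned `peak_table`.
#' @export
measure_chromatogram <- function(chrom, wavelength,
                                 library = default_library(),
                                 tolerance = 0.15, min_height = 0.1,
                                 min_prominence = 0.06, baseline_window = 2) {
  peaks <- detect_peaks(chrom, wavelength, min_height = min_height,
                        min_prominence = min_prominence,
                        baseline_window = baseline_window)
  assign_peaks(peaks, library, tolerance = tolerance)
}

#' Area attributed to one analyte in an assigned peak table
#'
#' Returns the area of the peak whose coelution group contains the analyte
#' (so the merged formic acid / glyceraldehyde peak answers for either name),
#' or `NA` when the analyte was not detected.
#'
#' @param peaks An assigned `peak_table`.
#' @param analyte Analyte name.
#' @return Area, or `NA_real_`.
#' @export
analyte_area <- function(peaks, analyte) {
  if (!nrow(peaks)) return(NA_real_)
  hit <- which(vapply(peaks$coelution_group, function(g) analyte %in% g,
                      logical(1)))
  if (!length(hit)) return(NA_real_)
  peaks$area[hit[which.max(peaks$area[hit])]]
}

#' Build a calibration curve from simulated standards
#'
#' Runs the full instrument path: simulate a calibration series, detect,
#' integrate and assign peaks at the requested wavelength, then fit the
#' area-concentration line.
#'
#' @inheritParams simulate_calibration_series
#' @param wavelength Detection wavelength (nm).
#' @param through_origin,sigma_mode Passed to [fit_calibration()].
#' @param grid Simulation time grid.
#' @return List with `curve` (a `calibration_curve`) and `points` (the
#'   measured area-concentration table).
#' @export
calibrate_simulated <- function(analyte, wavelength = 205,
                                levels = c(0.1, 0.5, 1.0, 2.5, 5.0),
                                replicates = 3,
                                library = default_library(),
                                noise = noise_model(),
                                through_origin = TRUE,
                                sigma_mode = "slope_sd",
                                grid = c(0, 30, 0.01)) {
  series <- simulate_calibration_series(analyte, levels, replicates,
                                        library = library, noise = noise,
                                        grid = grid)
  pts <- do.call(rbind, lapply(series, function(ch) {
    peaks <- measure_chromatogram(ch, wavelength, library = library)
    data.frame(concentration = ch$meta$known_concentration,
               area = analyte_area(peaks, analyte))
  }))
  if (anyNA(pts$area))
    stop("peak not detected in some calibration injections of ", analyte)
  curve <- fit_calibration(pts, through_origin = through_origin,
                           sigma_mode = sigma_mode, analyte = analyte,
                           wavelength = wavelength)
  list(curve = curve, points = pts)
}

#' Precision and recovery study from simulated standards
#'
#' Simulates triplicate standards at the repeatability levels (0.5, 2.5 and
#' 5 mM by default), quantifies them against a fitted curve and returns the
#' per-level RSD and recovery.
#'
#' @param analyte Analyte name.
#' @param curve Calibration curve used for quantification.
#' @inheritParams calibrate_simulated
#' @return List with `precision` (list of `precision_result`) and
#'   `recovery` (list of `recovery_result`).
#' @export
precision_recovery_study <- function(analyte, curve, wavelength = 205,
                                     levels = c(0.5, 2.5, 5),
                                     replicates = 3,
                                     library = default_library(),
                                     noise = noise_model(),
                                     grid = c(0, 30, 0.01)) {
  noise$seed <- if (is.null(noise$seed)) NULL
    else derive_seed(noise$seed, analyte, "precision")
  series <- simulate_calibration_series(analyte, levels, replicates,
                                        library = library, noise = noise,
                                        grid = grid)
  prec <- list(); rec <- list()
  for (lv in levels) {
    conc <- vapply(series, function(ch) {
      if (ch$meta$known_concentration != lv) return(NA_real_)
      peaks <- measure_chromatogram(ch, wavelength, library = library)
      as.numeric(quantify(analyte_area(peaks, analyte), curve))
    }, numeric(1))
    conc <- conc[!is.na(conc)]
    prec[[length(prec) + 1]] <- repeatability(conc, analyte, lv)
    rec[[length(rec) + 1]] <- recovery(conc, lv, analyte)
  }
  list(precision = prec, recovery = rec)
}

#' Validation of the indirect formic acid determination
#'
#' Reproduces the mixture-validation design: equimolar glyceraldehyde /
#' formic acid mixtures at the calibration levels, injected in triplicate.
#' Each injection is measured at both wavelengths; glyceraldehyde is
#' quantified from the 300 nm peak and formic acid by subtracting the
#' predicted glyceraldehyde area from the merged 205 nm area. Relative
#' errors against the prepared concentrations are reported per analyte.
#'
#' @param curves Named list with `glyald_300`, `glyald_205` and `fa_205`
#'   calibration curves.
#' @param levels Mixture concentrations (mM), equimolar in both analytes.
#' @param replicates Injections per level.
#' @inheritParams calibrate_simulated
#' @return Data frame with columns `level`, `replicate`, `analyte`,
#'   `expected`, `measured`, `error_pct`.
#' @export
indirect_fa_study <- function(curves, levels = c(0.1, 0.5, 1.0, 2.5, 5.0),
                              replicates = 3, library = default_library(),
                              noise = noise_model(), grid = c(0, 30, 0.01)) {
  rows <- list()
  for (li in seq_along(levels)) {
    for (rj in seq_len(replicates)) {
      nz <- noise
      nz$seed <- if (is.null(noise$seed)) NULL
        else derive_seed(noise$seed, "mixture", li, rj)
      ch <- simulate_injection(c(GlyAld = levels[li], FA = levels[li]),
                               library = library, noise = nz, grid = grid,
                               injection_id = sprintf("mix_L%02d_R%02d", li, rj))
      p300 <- measure_chromatogram(ch, 300, library = library)
      p205 <- measure_chromatogram(ch, 205, library = library)
      c_gly <- as.numeric(quantify_glyald(analyte_area(p300, "GlyAld"),
                                          curves$glyald_300))
      res <- indirect_fa(analyte_area(p205, "FA"), c_gly,
                         curves$glyald_205, curves$fa_205)
      rows[[length(rows) + 1]] <- data.frame(
        level = levels[li], replicate = rj,
        analyte = c("GlyAld", "FA"),
        expected = levels[li],
        measured = c(c_gly, res$c_fa))
    }
  }
  out <- do.call(rbind, rows)
  out$error_pct <- 100 * abs(out$measured - out$expected) / out$expected
  out
}

#' Quantify every panel product in an electrolysis chromatogram
#'
#' Measures both wavelengths, quantifies directly eluting products at
#' 205 nm, routes the merged 19.46 min peak through the two-wavelength
#' indirect method, and corrects all results back to cell concentrations
#' with the chromatogram's dilution factor. The salt peak and glycerol are
#' never counted as products; results below a curve's LOQ are flagged and,
#' by default, excluded.
#'
#' @param chrom An electrolysis [chromatogram()].
#' @param curves Named list of calibration curves keyed
#'   `"<analyte>@<wavelength>"` (e.g. `"OA@205"`, `"GlyAld@300"`); must
#'   contain `"GlyAld@205"` and `"FA@205"` for the indirect split whenever
#'   the merged peak is present.
#' @param library Compound library.
#' @param drop_below_loq Drop products flagged below LOQ (default `TRUE`).
#' @param tolerance Assignment tolerance (min).
#' @return List with `products` (named cell concentrations, mM),
#'   `below_loq` (named logical for all quantified species) and `peaks`
#'   (the assigned 205 nm peak table).
#' @export
quantify_electrolysis <- function(chrom, curves, library = default_library(),
                                  drop_below_loq = TRUE, tolerance = 0.15) {
  p205 <- measure_chromatogram(chrom, 205, library = library,
                               tolerance = tolerance)
  conc <- numeric(0); below <- logical(0)
  handled <- character(0)
  merged <- which(vapply(p205$coelution_group, function(g)
    all(c("FA", "GlyAld") %in% g), logical(1)))
  if (length(merged)) {
    p300 <- measure_chromatogram(chrom, 300, library = library,
                                 tolerance = tolerance)
    a300 <- analyte_area(p300, "GlyAld")
    c_gly <- if (is.na(a300)) 0
      else as.numeric(quantify_glyald(a300, curves[["GlyAld@300"]]))
    res <- indirect_fa(p205$area[merged[1]], c_gly,
                       curves[["GlyAld@205"]], curves[["FA@205"]])
    conc[c("GlyAld", "FA")] <- c(c_gly, res$c_fa)
    below[c("GlyAld", "FA")] <- c(
      c_gly < curves[["GlyAld@300"]]$loq, isTRUE(res$flags$below_loq))
    handled <- c("FA", "GlyAld")
  }
  for (k in seq_len(nrow(p205))) {
    an <- p205$assigned[k]
    if (is.na(an) || an %in% c(handled, "salt", "glycerol")) next
    key <- paste0(an, "@205")
    if (is.null(curves[[key]])) next
    ci <- quantify(p205$area[k], curves[[key]])
    conc[an] <- as.numeric(ci)
    below[an] <- attr(ci, "below_loq")
  }
  cell <- correct_dilution(conc, chrom$meta$dilution_factor)
  products <- if (drop_below_loq) cell[!below[names(cell)]] else cell
  list(products = products, below_loq = below, peaks = p205)
}
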