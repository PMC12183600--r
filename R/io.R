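#' Write a chromatogram to a text file
#'
#' Plain columnar format: '#'-prefixed header lines carrying metadata
#' (`matrix`, `dilution_factor`, `injection_id`, `seed`), then a
#' tab-delimited table with a `time_min` column and one `A<wavelength>`
#' column per trace. Numbers are written with 17 significant digits, so a
#' write/read round trip reproduces grids and traces exactly.
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# georquant chromatogram v1", con)
  writeLines(sprintf("# matrix: %s", chrom$meta$matrix), con)
  writeLines(sprintf("# dilution_factor: %.17g", chrom$meta$dilution_factor), con)
  writeLines(sprintf("# injection_id: %s", chrom$meta$injection_id), con)
  if (!is.null(chrom$meta$seed))
    writeLines(sprintf("# seed: %d", as.integer(chrom$meta$seed)), con)
  wl <- names(chrom$traces)
  writeLines(paste(c("time_min", paste0("A", wl)), collapse = "\t"), con)
  cols <- c(list(sprintf("%.17g", chrom$times)),
            lapply(chrom$traces, function(y) sprintf("%.17g", y)))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a chromatogram text file
#'
#' Counterpart of [write_chromatogram()]. Fails with the offending line
#' number when the time column is not strictly increasing.
#'
#' @param path File in the chromatogram text format.
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!is_hdr]
  if (length(body) < 2) stop("no data table in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "time_min") stop("first column must be time_min")
  tab <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = header, colClasses = "numeric")
  bad <- which(diff(tab$time_min) <= 0)
  if (length(bad)) {
    line_no <- which(!is_hdr)[1] + bad[1] + 1L
    stop("non-monotonic time column at line ", line_no, " of ", path)
  }
  wl <- sub("^A", "", header[-1])
  traces <- stats::setNames(lapply(header[-1], function(cn) tab[[cn]]), wl)
  m <- list(matrix = meta$matrix %||% "standard",
            dilution_factor = as.numeric(meta$dilution_factor %||% "1"),
            injection_id = meta$injection_id %||% "unnamed")
  if (!is.null(meta$seed)) m$seed <- as.integer(meta$seed)
  chromatogram(tab$time_min, traces, m)
}

#' Write a peak table
#'
#' Tab-delimited text plus a JSON twin (same base name, `.json` extension).
#' Formatting is deterministic: times to 3 decimals, areas and heights to 6
#' significant digits, stable row order.
#'
#' @param peaks A `peak_table` from [detect_peaks()] / [assign_peaks()].
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  out <- data.frame(
    injection_id = peaks$injection_id,
    analyte = ifelse(is.na(peaks$assigned), "unassigned", peaks$assigned),
    coelution_group = vapply(peaks$coelution_group, paste,
                             character(1), collapse = "+"),
    apex_time = sprintf("%.3f", peaks$apex_time),
    left_bound = sprintf("%.3f", peaks$left_bound),
    right_bound = sprintf("%.3f", peaks$right_bound),
    height = signif(peaks$height, 6),
    area = signif(peaks$area, 6),
    wavelength = peaks$wavelength,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out, sub("\\.[A-Za-z]+$", ".json", path),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a method validation report
#'
#' Emits a machine-readable JSON report and a rendered fixed-width table with
#' the classical validation layout: one column per analyte; rows for the
#' linearity range, the regression equation, the coefficient of
#' determination, LOD, LOQ, repeatability RSD at three levels and recovery at
#' three levels (13 metric rows). Concentrations are printed to 3 decimals
#' and percentages to 2; the JSON carries full precision plus the
#' sigma-mode provenance of each detection limit.
#'
#' @param curves List of `calibration_curve` objects, one per analyte.
#' @param precision Named list (by analyte) of lists of `precision_result`s.
#' @param recovery Named list (by analyte) of lists of `recovery_result`s.
#' @param path Output JSON path; the rendered table goes to the same base
#'   name with a `.txt` extension.
#' @return The in-memory report list, invisibly.
#' @export
write_validation_report <- function(curves, precision = list(),
                                    recovery = list(), path) {
  report <- list()
  for (curve in curves) {
    an <- curve$analyte
    entry <- list(
      analyte = an, wavelength = curve$wavelength,
      linearity_range = curve$conc_range %||% c(NA_real_, NA_real_),
      slope = curve$slope, slope_sd = curve$slope_sd,
      intercept = curve$intercept,
      equation = sprintf("y = (%.6g +/- %.3g)x%s", curve$slope, curve$slope_sd,
                         if (curve$through_origin) ""
                         else sprintf(" + %.6g", curve$intercept)),
      r_squared = curve$r_squared, sigma = curve$sigma,
      sigma_mode = curve$sigma_mode, lod = curve$lod, loq = curve$loq,
      n_points = curve$n_points)
    entry$rsd <- lapply(precision[[an]], function(p)
      list(level = p$level, rsd = p$rsd))
    entry$recovery <- lapply(recovery[[an]], function(r)
      list(level = r$level, recovery = r$recovery, sd = r$recovery_sd))
    report[[an]] <- entry
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(render_validation_table(report),
             sub("\\.[A-Za-z]+$", ".txt", path))
  invisible(report)
}

render_validation_table <- function(report) {
  if (!length(report)) return(character(0))
  analytes <- names(report)
  fmt3 <- function(x) sprintf("%.3f", x)
  fmt2 <- function(x) sprintf("%.2f", x)
  lvl_val <- function(entry, field, k, value, digits_fn) {
    items <- entry[[field]]
    if (length(items) >= k) digits_fn(items[[k]][[value]]) else ""
  }
  rows <- list(
    c("Parameter", analytes),
    c("Linearity range (mM)", vapply(report, function(e)
      sprintf("%g-%g", e$linearity_range[1], e$linearity_range[2]), "")),
    c("Linear regression equation", vapply(report, `[[`, "", "equation")),
    c("R2", vapply(report, function(e) sprintf("%.4f", e$r_squared), "")),
    c("LOD (mM)", vapply(report, function(e) fmt3(e$lod), "")),
    c("LOQ (mM)", vapply(report, function(e) fmt3(e$loq), "")),
    c("Repeatability (RSD, %)", rep("", length(analytes))))
  for (k in 1:3)
    rows[[length(rows) + 1]] <- c(
      sprintf("  level %d", k),
      vapply(report, lvl_val, "", field = "rsd", k = k, value = "rsd",
             digits_fn = fmt2))
  rows[[length(rows) + 1]] <- c("Recovery (R, %)", rep("", length(analytes)))
  for (k in 1:3)
    rows[[length(rows) + 1]] <- c(
      sprintf("  level %d", k),
      vapply(report, lvl_val, "", field = "recovery", k = k,
             value = "recovery", digits_fn = fmt2))
  mat <- do.call(rbind, rows)
  widths <- apply(nchar(mat), 2, max)
  apply(mat, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
}

#' Read and validate a run configuration
#'
#' JSON configuration mirroring the simulator, detection, calibration and
#' electrochemistry options. Unknown keys, at the top level or inside a
#' section, are rejected by name; missing keys fall back to package defaults.
#'
#' @param path JSON file.
#' @return Nested list of options merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- default_run_config()
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    extra <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(extra) && !sec %in% c("library"))
      stop("unknown key(s) in '", sec, "': ", paste(extra, collapse = ", "))
  }
  utils::modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    library = list(overrides = list(), extras = character(0)),
    noise = list(area_cv = 0.005, baseline_sd = 0.02, baseline_drift = 0,
                 seed = NULL),
    detection = list(min_height = 0.1, min_prominence = 0.06,
                     baseline_window = 2, tolerance = 0.15),
    calibration = list(through_origin = TRUE, sigma_mode = "slope_sd"),
    electrochem = list(volume_l = 0.010, charge_c = NA_real_,
                       selectivity_mode = "mole", dilution_factor = 1.25)
  )
}
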