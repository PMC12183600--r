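#' Construct a multi-wavelength chromatogram
#'
#' A chromatogram is a strictly increasing time grid (minutes) with one
#' absorbance trace per detection wavelength and acquisition metadata
#' (`matrix`: one of `"standard"`, `"alkaline"`, `"acidic"`;
#' `dilution_factor`; `injection_id`).
#'
#' @param times Strictly increasing numeric vector of times (min), length >= 2.
#' @param traces Named list of numeric absorbance vectors, names are
#'   wavelengths in nm; all the same length as `times`.
#' @param meta List of metadata; missing entries are filled with defaults.
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(times, traces, meta = list()) {
  if (length(times) < 2) stop("a chromatogram needs at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.list(traces) || is.null(names(traces)) || !all(nzchar(names(traces))))
    stop("`traces` must be a named list keyed by wavelength")
  if (!all(lengths(traces) == length(times)))
    stop("all traces must share the time grid")
  defaults <- list(matrix = "standard", dilution_factor = 1,
                   injection_id = "unnamed")
  meta <- utils::modifyList(defaults, meta)
  structure(list(times = as.numeric(times),
                 traces = lapply(traces, as.numeric),
                 meta = meta),
            class = "chromatogram")
}

#' Extract one absorbance trace
#'
#' @param chrom A [chromatogram()].
#' @param wavelength Wavelength in nm; must be present in the chromatogram.
#' @return Numeric absorbance vector on the chromatogram's time grid.
#' @export
chrom_trace <- function(chrom, wavelength) {
  key <- as.character(wavelength)
  if (!key %in% names(chrom$traces))
    stop("wavelength ", wavelength, " nm not present (have: ",
         paste(names(chrom$traces), collapse = ", "), ")")
  chrom$traces[[key]]
}

#' @export
print.chromatogram <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("chromatogram '%s': %d points, %.2f-%.2f min, %s nm, matrix=%s, dilution=%g\n",
              x$meta$injection_id, n, x$times[1], x$times[n],
              paste(names(x$traces), collapse = "/"),
              x$meta$matrix, x$meta$dilution_factor))
  invisible(x)
}
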