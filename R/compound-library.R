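#' The built-in GEOR analyte panel
#'
#' Returns the compound library for the glycerol electrooxidation (GEOR)
#' product panel measured by HPLC-DAD: the eight validated analytes (oxalic,
#' tartronic, glyceric, glycolic and formic acids, glyceraldehyde,
#' dihydroxyacetone and glycerol itself), optionally extended with lactic acid
#' and the alkaline-matrix salt pseudo-analyte. Each entry carries the
#' retention time (min), a Gaussian peak width (min), per-wavelength response
#' slopes (area units per mM), the number of electrons transferred per mole of
#' product formed from glycerol, the carbon count, and the validated linear
#' range (mM).
#'
#' Formic acid and glyceraldehyde share a retention time (19.46 min) by
#' construction: the pair co-elutes and is quantified with the two-wavelength
#' indirect method (see [indirect_fa()]). Response slopes not established on
#' the instrument (glyceraldehyde at 300 nm, lactic acid, the salt peak) are
#' synthetic defaults: they are configuration, not constants, and every
#' algorithm reads them from the library.
#'
#' @param overrides Named list of per-analyte field overrides, e.g.
#'   `list(GA = list(retention_time = 17.00))`. Valid fields are
#'   `retention_time`, `peak_sigma`, `response` (named numeric, names are
#'   wavelengths in nm; merged into the defaults), `z_electrons`, `n_carbons`
#'   and `linear_range` (length-2 numeric). Unknown analytes or fields are
#'   rejected by name.
#' @param extras Character vector of optional panel extensions, any of
#'   `"lactic"` (retention time 17.88 min) and `"salt"` (the alkaline-matrix
#'   salt peak at 11.38 min).
#' @return A `compound_library`: a data frame with one row per analyte and
#'   columns `analyte`, `retention_time`, `peak_sigma`, `response`
#'   (list-column of named numeric slopes), `z_electrons`, `n_carbons`,
#'   `range_low`, `range_high`.
#' @examples
#' lib <- default_library()
#' lib$retention_time[lib$analyte == "OA"]        # 12.37
#' response_slope(lib, "OA", 205)                 # 167894
#' default_library(list(GA = list(retention_time = 17.00)))
#' @export
default_library <- function(overrides = list(), extras = character()) {
  base <- .georquant_panel()
  if (length(extras))
    extras <- match.arg(extras, c("lactic", "salt"), several.ok = TRUE)
  keep <- c(.panel_core(), extras)
  base <- base[base$analyte %in% keep, , drop = FALSE]
  rownames(base) <- NULL

  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("`overrides` must be a named list keyed by analyte name")
    unknown <- setdiff(names(overrides), base$analyte)
    if (length(unknown))
      stop("unknown analyte(s) in overrides: ", paste(unknown, collapse = ", "))
    for (an in names(overrides)) {
      ov <- overrides[[an]]
      bad <- setdiff(names(ov), c("retention_time", "peak_sigma", "response",
                                  "z_electrons", "n_carbons", "linear_range"))
      if (length(bad))
        stop("unknown field(s) for ", an, ": ", paste(bad, collapse = ", "))
      i <- match(an, base$analyte)
      for (f in setdiff(names(ov), c("response", "linear_range")))
        base[[f]][i] <- ov[[f]]
      if (!is.null(ov$response)) {
        r <- base$response[[i]]
        r[names(ov$response)] <- ov$response
        base$response[[i]] <- r
      }
      if (!is.null(ov$linear_range)) {
        base$range_low[i] <- ov$linear_range[1]
        base$range_high[i] <- ov$linear_range[2]
      }
    }
  }
  validate_library(base)
}

.panel_core <- function() {
  c("OA", "TA", "GA", "GCA", "FA", "GlyAld", "DHA", "glycerol")
}

# Retention times and 205 nm slopes are the instrument's validated values;
# GlyAld@300, lactic and salt slopes are synthetic placeholders treated as data.
.georquant_panel <- function() {
  resp <- function(a205, a300 = 0) list(c(`205` = a205, `300` = a300))
  lib <- data.frame(
    analyte        = c("salt", "OA", "TA", "GA", "lactic", "GCA", "FA",
                       "GlyAld", "DHA", "glycerol"),
    retention_time = c(11.38, 12.37, 13.64, 17.13, 17.88, 18.31, 19.46,
                       19.46, 20.76, 22.46),
    peak_sigma     = rep(0.12, 10),
    z_electrons    = c(0, 22 / 3, 8, 4, 2, 10 / 3, 8 / 3, 2, 2, 0),
    n_carbons      = c(0L, 2L, 3L, 3L, 3L, 2L, 1L, 3L, 3L, 3L),
    range_low      = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 16),
    range_high     = c(50, 5, 5, 5, 5, 5, 5, 5, 5, 40),
    stringsAsFactors = FALSE
  )
  lib$response <- c(resp(5000), resp(167894), resp(34133), resp(9994),
                    resp(8000), resp(7441), resp(6309), resp(12566, 4000),
                    resp(17903), resp(30.6))
  class(lib) <- c("compound_library", "data.frame")
  lib
}

validate_library <- function(lib) {
  stopifnot(is.data.frame(lib), all(c("analyte", "retention_time", "peak_sigma",
                                      "response", "z_electrons", "n_carbons",
                                      "range_low", "range_high") %in% names(lib)))
  if (any(lib$retention_time <= 0)) stop("retention times must be positive")
  if (any(lib$peak_sigma <= 0)) stop("peak widths must be positive")
  if (any(unlist(lib$response) < 0)) stop("response slopes must be non-negative")
  if (any(lib$range_low >= lib$range_high))
    stop("linear_range low must be below high")
  if (anyDuplicated(lib$analyte)) stop("duplicate analyte names")
  class(lib) <- c("compound_library", "data.frame")
  lib
}

#' Look up a response slope
#'
#' @param lib A [default_library()]-style compound library.
#' @param analyte Analyte name.
#' @param wavelength Detection wavelength in nm.
#' @return Slope in area units per mM (0 when the analyte does not absorb at
#'   that wavelength).
#' @export
response_slope <- function(lib, analyte, wavelength) {
  i <- match(analyte, lib$analyte)
  if (is.na(i)) stop("analyte not in library: ", analyte)
  r <- lib$response[[i]]
  s <- r[as.character(wavelength)]
  if (is.na(s)) 0 else unname(s)
}

#' Wavelengths covered by a compound library
#' @param lib A compound library.
#' @return Sorted numeric vector of wavelengths (nm) with at least one entry.
#' @export
library_wavelengths <- function(lib) {
  sort(unique(as.numeric(unlist(lapply(lib$response, names)))))
}

#' @export
print.compound_library <- function(x, ...) {
  cat("GEOR compound library:", nrow(x), "analytes;",
      "wavelengths", paste(library_wavelengths(x), collapse = "/"), "nm\n")
  slopes <- vapply(seq_len(nrow(x)), function(i) x$response[[i]][["205"]], 0)
  print(data.frame(analyte = x$analyte, rt_min = x$retention_time,
                   sigma_min = x$peak_sigma, slope_205 = slopes,
                   z = round(x$z_electrons, 3), nC = x$n_carbons))
  invisible(x)
}
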