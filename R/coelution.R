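#' Quantify glyceraldehyde from its 300 nm peak
#'
#' Glyceraldehyde is the only panel member with usable absorbance at 300 nm,
#' so the merged 19.46 min peak is, at that wavelength, attributed entirely
#' to glyceraldehyde and quantified directly.
#'
#' @param area_300 Peak area at 300 nm.
#' @param curve_glyald_300 Calibration curve for GlyAld at 300 nm (checked).
#' @return Concentration in mM (see [quantify()] for flags).
#' @export
quantify_glyald <- function(area_300, curve_glyald_300) {
  check_curve(curve_glyald_300, "GlyAld", 300)
  quantify(area_300, curve_glyald_300)
}

check_curve <- function(curve, analyte, wavelength) {
  if (!is.na(curve$analyte) && curve$analyte != analyte)
    stop("curve is for ", curve$analyte, ", expected ", analyte)
  if (!is.na(curve$wavelength) && curve$wavelength != wavelength)
    stop("curve is at ", curve$wavelength, " nm, expected ", wavelength, " nm")
  invisible(curve)
}

#' Indirect determination of a co-eluting analyte (formic acid)
#'
#' Formic acid and glyceraldehyde co-elute at 19.46 min, so their 205 nm
#' areas add: `A_mix = A_GlyAld,205 + A_FA,205`. Glyceraldehyde is first
#' quantified at 300 nm; its expected 205 nm area is predicted from its
#' 205 nm calibration line, subtracted from the merged area, and the
#' remainder is converted to a formic acid concentration with formic acid's
#' 205 nm slope. The subtraction can produce small negative remainders at
#' trace levels under noise; these are clipped to zero and flagged rather
#' than raised, so batch runs never die. The deduced area is stored
#' unclipped, so the additivity identity
#' `a_mix_205 == a_glyald_205_pred + a_fa_205` holds exactly.
#'
#' The machinery generalises to any co-eluting pair in which one member has
#' a private wavelength; the GEOR formic acid / glyceraldehyde pair is the
#' default labelling.
#'
#' @param a_mix_205 Merged peak area at 205 nm.
#' @param c_glyald Concentration (mM) of the spectrally resolved member,
#'   from [quantify_glyald()]; must be >= 0.
#' @param curve_glyald_205 205 nm calibration curve of the resolved member.
#' @param curve_fa_205 205 nm calibration curve of the deduced member.
#' @return A `coelution_result`: list with `c_glyald`, `a_mix_205`,
#'   `a_glyald_205_pred`, `a_fa_205` (unclipped), `c_fa` (clipped to >= 0)
#'   and `flags` (`negative_area`, `below_loq`).
#' @examples
#' g205 <- manual_curve(12566, 50, analyte = "GlyAld", wavelength = 205)
#' f205 <- manual_curve(6309, 128, analyte = "FA", wavelength = 205)
#' indirect_fa(18875, 1, g205, f205)$c_fa  # 1 mM
#' @export
indirect_fa <- function(a_mix_205, c_glyald, curve_glyald_205, curve_fa_205) {
  if (c_glyald < 0) stop("c_glyald must be >= 0")
  check_curve(curve_glyald_205, curve_glyald_205$analyte %||% "GlyAld", 205)
  check_curve(curve_fa_205, curve_fa_205$analyte %||% "FA", 205)
  a_pred <- curve_glyald_205$slope * c_glyald + curve_glyald_205$intercept
  a_fa <- a_mix_205 - a_pred
  negative <- a_fa < 0
  c_fa <- quantify(max(a_fa, 0), curve_fa_205)
  structure(list(c_glyald = c_glyald, a_mix_205 = a_mix_205,
                 a_glyald_205_pred = a_pred, a_fa_205 = a_fa,
                 c_fa = as.numeric(c_fa),
                 flags = list(negative_area = negative,
                              below_loq = attr(c_fa, "below_loq"))),
            class = "coelution_result")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Relative quantification error
#'
#' `Error(%) = 100 * |E - T| / T` for an experimental value `E` against the
#' theoretical value `T`.
#'
#' @param experimental Measured value(s).
#' @param theoretical True value (> 0).
#' @return A `quant_error`: list with `experimental`, `theoretical`, `error`
#'   (percent).
#' @examples
#' percent_error(1.05, 1)$error  # 5
#' @export
percent_error <- function(experimental, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical value must be > 0")
  structure(list(experimental = experimental, theoretical = theoretical,
                 error = 100 * abs(experimental - theoretical) / theoretical),
            class = "quant_error")
}
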