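#' Faraday constant (C/mol)
#' @export
FARADAY <- 96485

#' Undo the acid-quench dilution
#'
#' Samples are quenched 1000 uL + 250 uL acid before injection, so measured
#' (injected) concentrations are converted back to cell concentrations by the
#' dilution factor, 1.25 by default.
#'
#' @param measured Measured concentration(s), mM.
#' @param dilution_factor Dilution factor (>= 1).
#' @return Cell concentration(s), mM.
#' @examples
#' correct_dilution(8)  # 10
#' @export
correct_dilution <- function(measured, dilution_factor = 1.25) {
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  measured * dilution_factor
}

#' Product selectivity distribution
#'
#' Percentage share of each quantified product. The default mole basis is
#' `100 * C_i / sum(C_j)`; a carbon basis weights each concentration by the
#' product's carbon count (share of converted carbon), an electron basis by
#' its electrons-per-mole (share of product-bound charge). Every basis sums
#' to 100.
#'
#' @param products Named numeric vector of concentrations (mM, >= 0; at
#'   least one positive).
#' @param mode `"mole"` (default), `"carbon"` or `"electron"`.
#' @param library Compound library supplying carbon counts and electron
#'   numbers.
#' @return Named numeric vector of percentages summing to 100.
#' @examples
#' selectivity(c(FA = 34, GCA = 8, GA = 7, OA = 0.5, TA = 0.5))
#' @export
selectivity <- function(products, mode = c("mole", "carbon", "electron"),
                        library = default_library()) {
  mode <- match.arg(mode)
  if (!length(products) || all(products <= 0))
    stop("no products: all concentrations are zero")
  if (any(products < 0)) stop("concentrations must be >= 0")
  unknown <- setdiff(names(products), library$analyte)
  if (length(unknown))
    stop("analyte(s) not in library: ", paste(unknown, collapse = ", "))
  i <- match(names(products), library$analyte)
  w <- switch(mode, mole = rep(1, length(products)),
              carbon = library$n_carbons[i],
              electron = library$z_electrons[i])
  x <- products * w
  100 * x / sum(x)
}

#' Assemble an electrolysis result
#'
#' Bundles dilution-corrected product concentrations with the cell volume,
#' the charge passed and the electrons-per-mole table, ready for selectivity
#' and Faradaic-efficiency reporting.
#'
#' @param products Named numeric vector of cell concentrations (mM).
#' @param volume_l Electrolyte volume in litres (> 0).
#' @param charge_c Charge passed in coulombs (> 0).
#' @param library Compound library; supplies `z_table` entries not given.
#' @param z_table Optional named override of electrons per mole.
#' @param matrix Matrix label carried through for reporting.
#' @return An `electrolysis_result` list.
#' @export
electrolysis_result <- function(products, volume_l, charge_c,
                                library = default_library(), z_table = NULL,
                                matrix = "alkaline") {
  if (volume_l <= 0) stop("volume_l must be > 0")
  if (charge_c <= 0) stop("charge_c must be > 0")
  if (any(products < 0)) stop("concentrations must be >= 0")
  z <- stats::setNames(library$z_electrons, library$analyte)
  if (!is.null(z_table)) z[names(z_table)] <- z_table
  structure(list(products = products, volume_l = volume_l,
                 charge_c = charge_c, faraday = FARADAY,
                 z_table = z, matrix = matrix),
            class = "electrolysis_result")
}

#' Faradaic efficiency
#'
#' Fraction of the passed charge accounted for by the quantified products:
#' `FE(%) = 100 * F * sum_i z_i C_i V / Q`, with `C_i` in mol/L (converted
#' from mM), `V` the cell volume and `z_i` the electrons transferred per mole
#' of product `i` formed from glycerol. Products invisible to the detector
#' (gaseous carbon dioxide or oxygen at high potential) depress the value
#' below 100%; the shortfall is reported as-is.
#'
#' @param result An [electrolysis_result()].
#' @return Efficiency in percent.
#' @examples
#' r <- electrolysis_result(c(FA = 1), volume_l = 1, charge_c = 8 / 3 * 96485 * 1e-3)
#' faradaic_efficiency(r)  # 100
#' @export
faradaic_efficiency <- function(result) {
  pr <- result$products
  pr <- pr[pr > 0]
  miss <- names(pr)[is.na(result$z_table[names(pr)])]
  if (length(miss))
    stop("no electrons-per-mole entry for: ", paste(miss, collapse = ", "))
  z <- result$z_table[names(pr)]
  mol <- pr * 1e-3 * result$volume_l
  100 * result$faraday * sum(z * mol) / result$charge_c
}

#' Charge passed as a fraction of full conversion
#'
#' `100 * Q / (z F C0 V)`: the passed charge relative to what full
#' conversion of the starting glycerol (concentration `c0_mM`) into a
#' product requiring `z` electrons per mole would need. Useful to place an
#' electrolysis on the partial-conversion scale (e.g. ~52% of the
#' two-electron conversion of 50 mM glycerol at 50 C in a 10 mL cell).
#'
#' @param c0_mM Initial substrate concentration, mM.
#' @param volume_l Electrolyte volume, litres.
#' @param z Electrons per mole for the reference transformation.
#' @param charge_c Charge passed, coulombs.
#' @return Percent of the full-conversion charge.
#' @examples
#' charge_fraction(50, 0.010, 2, 50)  # ~51.8
#' @export
charge_fraction <- function(c0_mM, volume_l, z, charge_c) {
  if (c0_mM <= 0 || volume_l <= 0 || z <= 0) stop("inputs must be > 0")
  100 * charge_c / (z * FARADAY * c0_mM * 1e-3 * volume_l)
}

#' @export
print.electrolysis_result <- function(x, ...) {
  cat(sprintf("electrolysis (%s): %.3g C over %.3g L\n",
              x$matrix, x$charge_c, x$volume_l))
  sel <- selectivity(x$products[x$products > 0])
  for (an in names(sel))
    cat(sprintf("  %-9s %7.3f mM  %5.1f %%\n", an, x$products[[an]], sel[[an]]))
  cat(sprintf("  Faradaic efficiency: %.1f %%\n", faradaic_efficiency(x)))
  invisible(x)
}
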