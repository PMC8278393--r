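#' @section Intensity unit conversions:
#' The commonly reported IR intensity units fall into two families. Band
#' strengths are linear multiples of mu_I^Q: its SI value (C^2 kg^-1), the
#' debye/angstrom/amu view (D^2 A^-2 amu^-1), the Napierian integrated
#' molecular attenuation coefficient A_I = N_A mu_I^Q / (12 eps0 c^2)
#' (m mol^-1) and its km mol^-1 variant. Attenuation coefficients
#' (m^2 mol^-1 and L mol^-1 cm^-1) are functions of wavenumber whose shape
#' depends on the lineshape; a bare number in one of them converts to the
#' other by the factor 10, but not to a band strength without the lineshape
#' (the link is the band integral, int eps d(nu) = A_I / ln 10). The
#' conversion engine therefore converts freely within each family and raises
#' an informative error across families. All factors are computed from the
#' CODATA constants at call time; none is a hard-coded literal.
#' @name pe-units
#' @keywords internal
NULL

# factors are kept as (base mantissa, power of ten) so that conversions
# related by an exact decimal step (km vs m, L mol^-1 cm^-1 vs m^2 mol^-1)
# are exact in floating point, not just close
unit_family <- function(tags, base, exp10) {
  data.frame(tag = tags, base = base, exp10 = exp10,
             stringsAsFactors = FALSE)
}

ir_strength_factors <- function() {
  f <- pe_unit_factors()
  unit_family(c("C2/kg", "D2/A2/amu", "m/mol", "km/mol"),
              base = c(1, f$mu_q_si_to_d2a2amu, f$napierian_per_mu_q,
                       f$napierian_per_mu_q),
              exp10 = c(0, 0, 0, -3))
}

ir_coefficient_factors <- function() {
  unit_family(c("m2/mol", "L/mol/cm"), base = c(1, 1), exp10 = c(0, 1))
}

raman_strength_factors <- function() {
  f <- pe_unit_factors()
  unit_family(c("C4m2/J2kg", "m4/kg", "A4/amu"),
              base = c(1, (1 / (4 * pi * pe_constants$eps0))^2,
                       f$alpha_q_si_to_a4amu),
              exp10 = c(0, 0, 0))
}

convert_with <- function(value, from, to, families, what) {
  for (fam in families) {
    if (from %in% fam$tag && to %in% fam$tag) {
      i <- match(from, fam$tag); j <- match(to, fam$tag)
      ratio <- if (fam$base[j] == fam$base[i]) 1 else fam$base[j] / fam$base[i]
      return(value * ratio * 10^(fam$exp10[j] - fam$exp10[i]))
    }
  }
  all_tags <- unlist(lapply(families, function(f) f$tag))
  if (!from %in% all_tags) stop("unknown ", what, " unit: ", from)
  if (!to %in% all_tags) stop("unknown ", what, " unit: ", to)
  stop("cannot convert ", what, " value from '", from, "' to '", to,
       "': the units belong to different families (band strength vs ",
       "wavenumber-dependent coefficient); the link between them is the ",
       "band integral and requires the lineshape")
}

#' Convert IR intensity values between reported unit conventions
#'
#' @param value Numeric value(s).
#' @param from,to Unit tags among `"C2/kg"`, `"D2/A2/amu"`, `"m/mol"`,
#'   `"km/mol"` (band strengths) and `"m2/mol"`, `"L/mol/cm"` (attenuation
#'   coefficients).
#' @return Converted value(s).
#' @examples
#' convert_ir_units(1, "C2/kg", "D2/A2/amu")  # ~1.4924e12
#' convert_ir_units(1, "m/mol", "km/mol")     # 1e-3
#' @export
convert_ir_units <- function(value, from, to) {
  convert_with(value, from, to,
               list(ir_strength_factors(), ir_coefficient_factors()),
               "IR intensity")
}

#' Convert Raman intensity values between reported unit conventions
#'
#' @inheritParams convert_ir_units
#' @param from,to Unit tags among `"C4m2/J2kg"`, `"m4/kg"`, `"A4/amu"`
#'   (polarizability-gradient strengths). The absolute differential cross
#'   section additionally depends on the incident wavenumber and temperature
#'   and is computed by [raman_cross_section()], not by a unit factor.
#' @examples
#' convert_raman_units(1, "C4m2/J2kg", "A4/amu")  # ~1.3413e33
#' @export
convert_raman_units <- function(value, from, to) {
  convert_with(value, from, to, list(raman_strength_factors()),
               "Raman intensity")
}
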