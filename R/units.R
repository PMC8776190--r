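#' @keywords internal
"_PACKAGE"

# Molar volume of an ideal gas at 25 degrees C and 101.325 kPa, L/mol.
# Standard industrial-hygiene convention for ppm <-> mg/m3 conversion.
MOLAR_VOLUME_25C <- 24.45

.hazmix_units <- c("mg_per_m3", "ppm", "fibers_per_cm3")
.oel_kinds <- c("eight_hour", "short_term", "ceiling")

#' Convert an airborne concentration between ppm and mg/m3
#'
#' Uses the ideal-gas relation at 25 degrees C and 101.325 kPa:
#' mg/m3 = ppm * MW / 24.45, where MW is the molecular weight in g/mol.
#' Identity when `from_unit == to_unit` (molecular weight then unused).
#' Fibre counts (`fibers_per_cm3`) have no mass equivalence and can only
#' pass through the identity case.
#'
#' @param value Concentration magnitude (>= 0).
#' @param from_unit,to_unit One of `"ppm"`, `"mg_per_m3"`, or
#'   `"fibers_per_cm3"` (identity only).
#' @param molecular_weight g/mol; required when units differ.
#' @param substance Optional label used in error messages.
#' @return The value expressed in `to_unit`.
#' @examples
#' convert_concentration(10, "ppm", "mg_per_m3", molecular_weight = 92.14)
#' @export
convert_concentration <- function(value, from_unit, to_unit,
                                  molecular_weight = NULL,
                                  substance = NULL) {
  from_unit <- match.arg(from_unit, .hazmix_units)
  to_unit <- match.arg(to_unit, .hazmix_units)
  if (from_unit == to_unit) {
    return(value)
  }
  who <- if (is.null(substance)) "" else paste0(" for substance ", substance)
  if (from_unit == "fibers_per_cm3" || to_unit == "fibers_per_cm3") {
    stop("cannot convert between fibre counts and mass/volume units",
         who, call. = FALSE)
  }
  if (is.null(molecular_weight) || is.na(molecular_weight)) {
    stop("unit mismatch (", from_unit, " vs ", to_unit,
         ") and molecular weight is missing", who, call. = FALSE)
  }
  if (from_unit == "ppm") {
    value * molecular_weight / MOLAR_VOLUME_25C
  } else {
    value * MOLAR_VOLUME_25C / molecular_weight
  }
}
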