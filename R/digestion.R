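#' Back-calculate original-sample concentration from an instrument reading
#'
#' Converts a solution concentration measured by the spectrometer into the
#' concentration in the original (pre-digestion) sample:
#'
#'   C_final = C_inst x DF x V / W
#'
#' where C_inst is the solution concentration (ug/L), DF the dilution
#' factor applied ahead of analysis, V the returned volume of the digest
#' and W the mass of sample weighed into the digestion vessel. Volumes are
#' supplied in mL and masses in g; both are converted to L and kg here, at
#' the single conversion point of the package, so the result is in ug/kg.
#'
#' @param c_inst solution concentration, ug/L.
#' @param dilution_factor pre-analysis dilution factor (default 5).
#' @param returned_volume_ml returned digest volume, mL. No default: the
#'   returned volume is a per-sample measurement and is never assumed.
#' @param weighed_mass_g digested sample mass, g.
#' @return concentration in the original sample, ug/kg.
#' @examples
#' back_calculate(1.0, 5, returned_volume_ml = 10, weighed_mass_g = 0.5)
#' @seealso [forward_reading()] for the algebraic inverse.
#' @export
back_calculate <- function(c_inst, dilution_factor = 5,
                           returned_volume_ml, weighed_mass_g) {
  check_digestion_args(c_inst, dilution_factor, returned_volume_ml,
                       weighed_mass_g)
  c_inst * dilution_factor * (returned_volume_ml / 1000) /
    (weighed_mass_g / 1000)
}

#' Solution concentration that a given sample concentration would produce
#'
#' Algebraic inverse of [back_calculate()], used by the synthetic panel
#' generator to turn assumed true sample concentrations into
#' instrument-level readings:
#'
#'   C_inst = C_final x W / (DF x V)
#'
#' @inheritParams back_calculate
#' @param c_final concentration in the original sample, ug/kg.
#' @return solution concentration, ug/L.
#' @export
forward_reading <- function(c_final, dilution_factor = 5,
                            returned_volume_ml, weighed_mass_g) {
  check_digestion_args(c_final, dilution_factor, returned_volume_ml,
                       weighed_mass_g)
  c_final * (weighed_mass_g / 1000) /
    (dilution_factor * (returned_volume_ml / 1000))
}

check_digestion_args <- function(conc, df, vol, mass) {
  if (any(conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (any(df <= 0)) stop("dilution factor must be positive", call. = FALSE)
  if (missing(vol) || any(!is.finite(vol)) || any(vol <= 0)) {
    stop("returned volume (mL) must be supplied and positive", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("weighed mass (g) must be supplied and positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Back-calculate a table of instrument readings
#'
#' @param readings tibble with columns `sample_id`, `element`,
#'   `c_inst_ug_per_L`, `df`, `returned_volume_ml`, `weighed_mass_g`.
#' @return the same tibble with a `conc_ug_per_kg` column appended.
#' @export
back_calculate_readings <- function(readings) {
  needed <- c("sample_id", "element", "c_inst_ug_per_L", "df",
              "returned_volume_ml", "weighed_mass_g")
  missing <- setdiff(needed, names(readings))
  if (length(missing) > 0) {
    stop("readings table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  readings$conc_ug_per_kg <- back_calculate(
    readings$c_inst_ug_per_L, readings$df,
    readings$returned_volume_ml, readings$weighed_mass_g)
  readings
}
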