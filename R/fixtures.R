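#' Packaged reference panel of 36 protein powder samples
#'
#' A transcription of a published market survey of commercial protein
#' powder supplements (whey, pea, soy, mixed plant, whey/soy/egg blend and
#' casein) analysed by ICP-SFMS after microwave acid digestion: per-sample
#' concentrations for 20 elements in ug/kg (Mg exceeded the calibration
#' range in every sample and is absent), together with serving masses and
#' digested sample weights. Left-censored results are recorded with their
#' reporting limits and above-range results are flagged as such.
#'
#' @return An `element_panel` (see [load_panel()]).
#' @examples
#' panel <- reference_panel()
#' subset(panel$concentrations, sample_id == "P1" & element == "Cd")
#' @export
reference_panel <- function() {
  load_panel(
    system.file("extdata", "protein_panel_concentrations.csv",
                package = "elemrisk", mustWork = TRUE),
    system.file("extdata", "protein_panel_metadata.csv",
                package = "elemrisk", mustWork = TRUE)
  )
}

#' Toxicological reference table
#'
#' Oral reference doses (RfD, ug per kg body weight per day), cancer slope
#' factors (CSF, per ug per kg body weight per day), recommended dietary
#' allowances and tolerable upper intake levels (ug/day) where established,
#' plus membership flags for the hazard-index element list (`in_hi_list`,
#' 15 elements) and the carcinogenic-risk list (`in_cr_list`: Be, Cd, Pb).
#' Total Cr carries the Cr(VI) RfD/CSF values for reference but is flagged
#' out of both lists because the assay measures total Cr.
#'
#' @return A tibble, one row per panel element.
#' @export
tox_reference <- function() {
  path <- system.file("extdata", "tox_reference.csv",
                      package = "elemrisk", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    element = readr::col_character(),
    rfd = readr::col_double(),
    csf = readr::col_double(),
    rda = readr::col_double(),
    ul = readr::col_double(),
    in_hi_list = readr::col_logical(),
    in_cr_list = readr::col_logical(),
    note = readr::col_character()
  ), progress = FALSE)
}

#' Packaged instrument QC recoveries
#'
#' Percent recoveries (with replicate RSDs) of matrix-spiked controls and
#' calibration readback standards at five concentration levels spanning
#' the calibration range, as used to verify accuracy of the panel
#' measurements.
#'
#' @return A tibble with columns `element`, `level_ug_per_L`,
#'   `rec_percent`, `rsd_percent`, `n`, `control_kind`, `note`.
#' @export
qc_recoveries <- function() {
  path <- system.file("extdata", "qc_recoveries.csv",
                      package = "elemrisk", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    element = readr::col_character(),
    level_ug_per_L = readr::col_double(),
    rec_percent = readr::col_double(),
    rsd_percent = readr::col_double(),
    n = readr::col_integer(),
    control_kind = readr::col_character(),
    note = readr::col_character()
  ), progress = FALSE)
}

#' Default limit-of-quantification censoring limits
#'
#' Reporting limits (ug/kg in the original sample) at which the reference
#' panel records left-censored results. Elements never censored in the
#' panel are absent.
#'
#' @return named numeric vector.
#' @export
default_loq_limits <- function() {
  c(Li = 17.4, Be = 0.9, Sn = 17.4, Hg = 0.2, Cd = 0.61, Bi = 0.1, V = 0.6)
}
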