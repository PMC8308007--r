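#' The 21-element analytical panel
#'
#' Chemical symbols of the elements covered by the ICP-SFMS panel. All
#' concentration tables are validated against this set; isotope-labelled
#' column headers (e.g. `"7Li"`, `"208Pb"`) are accepted on input and
#' normalised to plain symbols.
#'
#' @format A character vector of 21 chemical symbols.
#' @export
panel_elements <- c(
  "Al", "Au", "Ba", "Be", "Bi", "Cd", "Co", "Cr", "Cu", "Fe", "Hg",
  "Li", "Mg", "Mn", "Mo", "Pb", "Pt", "Sn", "Ti", "Tl", "V"
)

#' Elements entering the hazard-index sum
#'
#' The 15 elements with established oral reference doses whose hazard
#' quotients are summed into the hazard index. Total Cr is excluded even
#' though an RfD exists for Cr(VI), because the assay determines total Cr.
#'
#' @export
hi_elements <- c(
  "Li", "Be", "Mo", "Cd", "Sn", "Ba", "Hg", "Tl", "Pb",
  "Al", "V", "Mn", "Fe", "Co", "Cu"
)

#' Elements entering the carcinogenic-risk assessment
#'
#' Elements with established cancer slope factors retained for CR
#' calculation. Cr(VI) has a slope factor but total Cr is omitted.
#'
#' @export
cr_elements <- c("Be", "Cd", "Pb")

#' Normalise element labels to chemical symbols
#'
#' Strips isotope mass numbers written as plain digits, carets or Unicode
#' superscripts (`"7Li"`, `"^208^Pb"`, `"\u2077Li"` (superscripts)) and validates the
#' result against [panel_elements].
#'
#' @param x character vector of element or isotope labels.
#' @return character vector of chemical symbols.
#' @examples
#' normalise_element(c("7Li", "208Pb", "Cd"))
#' @export
normalise_element <- function(x) {
  sym <- gsub("[0-9^\u2070-\u2079\u00b9\u00b2\u00b3[:space:]]", "", x)
  bad <- !(sym %in% panel_elements)
  if (any(bad)) {
    stop("unknown element column(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  sym
}
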