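#' Estimated daily intake
#'
#' EDI = C x IR / BW, where C is the resolved concentration in the product
#' (ug/kg), IR the daily intake of product (kg/day: serving mass times the
#' number of servings) and BW the consumer body weight (kg). The result is
#' in ug per kg body weight per day.
#'
#' @param conc resolved concentration, ug/kg (see [apply_censor_policy()]).
#' @param serving_mass_g mass of one serving, g.
#' @param servings servings per day (default 1).
#' @param body_weight body weight, kg (default 70).
#' @return EDI in ug/kg BW/day.
#' @examples
#' compute_edi(5.6, serving_mass_g = 60)        # ~4.8e-3
#' compute_edi(58.1, serving_mass_g = 60)       # ~0.05
#' @export
compute_edi <- function(conc, serving_mass_g, servings = 1, body_weight = 70) {
  stopifnot(all(serving_mass_g > 0), all(servings >= 1), all(body_weight > 0))
  conc * (serving_mass_g / 1000 * servings) / body_weight
}

#' Hazard quotient
#'
#' HQ = EDI / RfD. Values above 1 indicate intake above the oral reference
#' dose, i.e. potential for non-carcinogenic effects.
#'
#' @param edi estimated daily intake, ug/kg BW/day.
#' @param rfd oral reference dose, ug/kg BW/day; must be positive.
#' @return dimensionless hazard quotient.
#' @export
compute_hq <- function(edi, rfd) {
  if (any(rfd <= 0, na.rm = TRUE)) stop("RfD must be positive", call. = FALSE)
  edi / rfd
}

#' Carcinogenic risk from a slope factor
#'
#' Combines an estimated daily intake with an element's cancer slope
#' factor. Two conventions are implemented:
#'
#' * `"table_match"` (default): CR = EDI / CSF, where CSF is taken as a
#'   constant on the intake scale. This is the convention that reproduces
#'   the published screening tables this package ships as fixtures.
#' * `"literal_eq5"`: CR = EDI x CSF, the textbook slope-factor product.
#'
#' The two differ by a factor of CSF squared; reports always name the
#' convention used.
#'
#' @param edi estimated daily intake, ug/kg BW/day.
#' @param csf cancer slope factor; must be positive.
#' @param convention `"table_match"` or `"literal_eq5"`.
#' @return dimensionless lifetime incremental cancer risk.
#' @examples
#' edi <- compute_edi(5.6, serving_mass_g = 60)
#' compute_cr(edi, csf = 4300)   # ~1.1e-6
#' @export
compute_cr <- function(edi, csf,
                       convention = c("table_match", "literal_eq5")) {
  convention <- match.arg(convention)
  if (any(csf <= 0, na.rm = TRUE)) stop("CSF must be positive", call. = FALSE)
  switch(convention,
         table_match = edi / csf,
         literal_eq5 = edi * csf)
}

#' Classify a hazard index
#'
#' `"elevated"` strictly above 1, `"low"` otherwise (a product at exactly
#' HI = 1 is not flagged).
#'
#' @param hi hazard index values.
#' @return character vector `"low"`/`"elevated"`.
#' @export
classify_hi <- function(hi) {
  stopifnot(all(hi >= 0, na.rm = TRUE))
  ifelse(hi > 1, "elevated", "low")
}

#' Classify a cancer risk
#'
#' `"low"` at or below the threshold (default 1e-4, the conventional
#' regulatory-concern level), `"elevated"` strictly above it.
#'
#' @param cr cancer risk values.
#' @param threshold classification cut (inclusive on the low side).
#' @return character vector `"low"`/`"elevated"`.
#' @export
classify_cr <- function(cr, threshold = 1e-4) {
  stopifnot(all(cr >= 0, na.rm = TRUE))
  ifelse(cr > threshold, "elevated", "low")
}

#' Percent of a reference intake
#'
#' Expresses an intake as a percentage of a reference value (RfD, RDA or
#' UL) on the same scale.
#'
#' @param edi intake.
#' @param reference positive reference value.
#' @return 100 x edi / reference.
#' @export
percent_of_reference <- function(edi, reference) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  100 * edi / reference
}

#' Full exposure and risk assessment of a panel
#'
#' Runs the whole screening pipeline over an [`element_panel`][load_panel]:
#' resolves censored concentrations under the configured policy, computes
#' per-element estimated daily intakes, hazard quotients for the
#' hazard-index element list, per-sample hazard indices, and slope-factor
#' cancer risks for the carcinogenic-risk element list, at each requested
#' serving count.
#'
#' Above-range (not quantifiable) results and elements lacking the needed
#' reference value contribute nothing to the sums; affected rows are kept
#' in the exposure table with `excluded = TRUE` so the resulting
#' under-estimation is visible, and each sample's hazard index carries the
#' count of excluded hazard-list elements.
#'
#' @param panel an `element_panel`.
#' @param tox toxicological reference table (default [tox_reference()]).
#' @param config an [assessment_config()].
#' @param servings integer vector of serving counts to evaluate.
#' @return An object of class `risk_assessment`: list with
#'   * `exposure`: tidy tibble, one row per sample x element x servings,
#'     with `conc`, `excluded`, `edi`, `hq`, `cr`;
#'   * `hi`: per sample x servings hazard index, exclusion count and
#'     classification;
#'   * `cr`: per sample x carcinogenic element x servings risk and
#'     classification;
#'   * `config`, `servings` as supplied.
#' @examples
#' res <- assess_panel(reference_panel())
#' subset(res$hi, sample_id == "P1")
#' @export
assess_panel <- function(panel, tox = tox_reference(),
                         config = assessment_config(), servings = c(1L, 3L)) {
  stopifnot(inherits(panel, "element_panel"), all(servings >= 1))
  conc <- panel$concentrations
  conc$conc <- apply_censor_policy(conc$status, conc$value, conc$limit,
                                   policy = config$censor_policy,
                                   above_range_policy = config$above_range_policy)
  conc <- dplyr::left_join(conc, panel$metadata, by = "sample_id")
  conc <- dplyr::left_join(
    conc, tox[, c("element", "rfd", "csf", "in_hi_list", "in_cr_list")],
    by = "element")
  conc$in_hi_list[is.na(conc$in_hi_list)] <- FALSE
  conc$in_cr_list[is.na(conc$in_cr_list)] <- FALSE

  per_serving <- lapply(servings, function(k) {
    d <- conc
    d$servings <- as.integer(k)
    d$excluded <- is.na(d$conc)
    d$edi <- ifelse(d$excluded, NA_real_,
                    compute_edi(d$conc, d$serving_mass_g, k,
                                config$body_weight))
    d$hq <- ifelse(d$in_hi_list & !d$excluded,
                   compute_hq(d$edi, d$rfd), NA_real_)
    d$cr <- ifelse(d$in_cr_list & !d$excluded,
                   compute_cr(d$edi, d$csf, config$cr_convention), NA_real_)
    d
  })
  exposure <- dplyr::bind_rows(per_serving)
  exposure <- dplyr::select(
    exposure, "sample_id", "protein_type", "element", "servings",
    "status", "conc", "excluded", "edi", "hq", "cr")

  hi <- dplyr::summarise(
    dplyr::group_by(exposure[exposure$element %in% tox$element[tox$in_hi_list], ],
                    .data$sample_id, .data$protein_type, .data$servings),
    hi = sum(.data$hq, na.rm = TRUE),
    n_excluded = sum(.data$excluded),
    .groups = "drop")
  hi$class <- classify_hi(hi$hi)

  cr <- exposure[!is.na(exposure$cr) | (exposure$element %in%
                   tox$element[tox$in_cr_list]), ]
  cr <- cr[cr$element %in% tox$element[tox$in_cr_list], ]
  cr <- dplyr::select(cr, "sample_id", "protein_type", "element",
                      "servings", "excluded", "cr")
  # censored carcinogens resolved to zero intake carry zero risk; only
  # above-range exclusions stay NA
  cr$class <- ifelse(is.na(cr$cr), NA_character_, classify_cr(cr$cr))

  structure(list(exposure = exposure, hi = hi, cr = cr,
                 config = config, servings = as.integer(servings)),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment> ", length(unique(x$hi$sample_id)), " samples, ",
      "servings/day: ", paste(x$servings, collapse = ", "), "\n", sep = "")
  cat("  censor policy: ", x$config$censor_policy,
      "; CR convention: ", x$config$cr_convention, "\n", sep = "")
  for (k in x$servings) {
    n_ex <- sum(x$hi$hi > 1 & x$hi$servings == k)
    cat("  HI > 1 at ", k, " serving(s): ", n_ex, " of ",
        length(unique(x$hi$sample_id)), " samples\n", sep = "")
  }
  invisible(x)
}

#' Per-sample hazard index
#'
#' Convenience wrapper around [assess_panel()] returning just the hazard
#' indices.
#'
#' @inheritParams assess_panel
#' @return tibble with `sample_id`, `protein_type`, `servings`, `hi`,
#'   `n_excluded`, `class`.
#' @export
compute_hi <- function(panel, tox = tox_reference(),
                       config = assessment_config(), servings = c(1L, 3L)) {
  assess_panel(panel, tox, config, servings)$hi
}

#' Count samples above a risk threshold
#'
#' @param assessment a `risk_assessment`.
#' @param metric `"hi"` or `"cr"`.
#' @param threshold exceedance cut; samples strictly above it are counted.
#' @param servings serving count at which to evaluate.
#' @param element carcinogenic element (required for `metric = "cr"`).
#' @return integer count of exceeding samples.
#' @examples
#' res <- assess_panel(reference_panel())
#' count_exceedances(res, "hi", threshold = 1, servings = 3)
#' @export
count_exceedances <- function(assessment, metric = c("hi", "cr"),
                              threshold, servings = 1L, element = NULL) {
  metric <- match.arg(metric)
  if (metric == "hi") {
    d <- assessment$hi[assessment$hi$servings == servings, ]
    sum(d$hi > threshold)
  } else {
    if (is.null(element)) stop("element is required for metric = 'cr'",
                               call. = FALSE)
    d <- assessment$cr[assessment$cr$servings == servings &
                         assessment$cr$element == element, ]
    sum(d$cr > threshold, na.rm = TRUE)
  }
}

#' Wide hazard-index table
#'
#' @param assessment a `risk_assessment`.
#' @return tibble with one row per sample and one HI column per serving
#'   count, HI rounded to 3 decimals for reporting.
#' @export
hi_table <- function(assessment) {
  wide <- tidyr::pivot_wider(
    assessment$hi[, c("sample_id", "protein_type", "servings", "hi")],
    names_from = "servings", values_from = "hi",
    names_prefix = "hi_servings_")
  dplyr::mutate(wide, dplyr::across(dplyr::starts_with("hi_servings_"),
                                    ~ round(.x, 3)))
}

#' Wide cancer-risk table
#'
#' @param assessment a `risk_assessment`.
#' @return tibble with one row per sample and one column per carcinogenic
#'   element x serving count, CR rounded to 2 significant figures.
#' @export
cr_table <- function(assessment) {
  d <- assessment$cr[, c("sample_id", "protein_type", "element",
                         "servings", "cr")]
  d$cr <- signif(d$cr, 2)
  tidyr::pivot_wider(d, names_from = c("element", "servings"),
                     values_from = "cr", names_glue = "cr_{element}_{servings}")
}
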