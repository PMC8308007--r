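#' @importFrom rlang .data
NULL

# Parse raw concentration cells ("12.3", "<17.4", "NR*") into the
# status/value/limit triple used throughout the package.
parse_concentration_cells <- function(cells, element) {
  cells <- trimws(as.character(cells))
  status <- rep(NA_character_, length(cells))
  value <- rep(NA_real_, length(cells))
  limit <- rep(NA_real_, length(cells))

  is_na <- is.na(cells) | cells == "" | toupper(cells) == "NA"
  is_nr <- grepl("^NR\\*?$", cells, ignore.case = TRUE)
  is_cens <- grepl("^<", cells)

  status[is_nr] <- "above_range"
  limit[is_cens] <- as.numeric(sub("^<", "", cells[is_cens]))
  status[is_cens] <- "below_limit"

  plain <- !(is_na | is_nr | is_cens)
  value[plain] <- suppressWarnings(as.numeric(cells[plain]))
  if (anyNA(value[plain])) {
    stop("unparseable concentration cell(s) for ", element, ": ",
         paste(cells[plain][is.na(value[plain])], collapse = ", "),
         call. = FALSE)
  }
  status[plain] <- "quantified"

  if (any(value < 0, na.rm = TRUE)) {
    stop("negative concentration for ", element, call. = FALSE)
  }
  if (any(limit <= 0, na.rm = TRUE)) {
    stop("non-positive censoring limit for ", element, call. = FALSE)
  }
  tibble::tibble(status = status, value = value, limit = limit)
}

#' Read a wide concentration table into tidy long format
#'
#' The expected layout is one row per sample and one column per element,
#' with cells that are either a number (quantified, ug/kg), `"<X"`
#' (left-censored below the reporting limit X) or `"NR*"` (above the
#' calibration range, not quantifiable). Empty cells mean the element was
#' not reported for that sample and are dropped.
#'
#' @param path CSV/TSV file; first column `sample_id`, remaining columns
#'   element symbols or isotope labels.
#' @return A tibble with columns `sample_id`, `element`, `status`
#'   (`"quantified"`, `"below_limit"` or `"above_range"`), `value` and
#'   `limit` (each populated only when its status applies).
#' @export
read_concentrations <- function(path) {
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  names(raw)[1] <- "sample_id"
  elems <- normalise_element(names(raw)[-1])
  names(raw)[-1] <- elems

  long <- tidyr::pivot_longer(raw, -"sample_id",
                              names_to = "element", values_to = "cell")
  parsed <- dplyr::group_modify(
    dplyr::group_by(long, .data$element),
    function(d, key) {
      cbind(d["sample_id"], cell = d$cell,
            parse_concentration_cells(d$cell, key$element))
    }
  )
  parsed <- dplyr::ungroup(parsed)
  parsed <- dplyr::filter(parsed, !is.na(.data$status))
  dplyr::select(parsed, "sample_id", "element", "status", "value", "limit")
}

guess_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read sample metadata
#'
#' @param path CSV/TSV with columns `sample_id`, `protein_type`,
#'   `serving_mass_g`, `weighed_mass_g` and optionally
#'   `returned_volume_ml`.
#' @return A tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_delim(path, delim = guess_delim(path),
                            col_types = readr::cols(
                              sample_id = readr::col_character(),
                              protein_type = readr::col_character(),
                              serving_mass_g = readr::col_double(),
                              weighed_mass_g = readr::col_double(),
                              .default = readr::col_guess()),
                            progress = FALSE)
  needed <- c("sample_id", "protein_type", "serving_mass_g", "weighed_mass_g")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(meta$serving_mass_g <= 0) || any(meta$weighed_mass_g <= 0)) {
    stop("serving_mass_g and weighed_mass_g must be positive", call. = FALSE)
  }
  if ("returned_volume_ml" %in% names(meta) &&
      any(meta$returned_volume_ml <= 0, na.rm = TRUE)) {
    stop("returned_volume_ml must be positive when present", call. = FALSE)
  }
  meta
}

#' Load a sample panel (concentrations + metadata)
#'
#' Couples a tidy concentration table with per-sample metadata and checks
#' that every measured sample has metadata.
#'
#' @param concentrations path to a wide concentration table (see
#'   [read_concentrations()]) or an already-parsed tidy tibble.
#' @param metadata path to a metadata table (see [read_metadata()]) or a
#'   tibble.
#' @return An object of class `element_panel`: a list with elements
#'   `concentrations` (tidy long tibble) and `metadata`.
#' @examples
#' panel <- reference_panel()
#' nrow(panel$metadata)
#' @export
load_panel <- function(concentrations, metadata) {
  conc <- if (is.character(concentrations)) {
    read_concentrations(concentrations)
  } else {
    tibble::as_tibble(concentrations)
  }
  meta <- if (is.character(metadata)) {
    read_metadata(metadata)
  } else {
    tibble::as_tibble(metadata)
  }
  orphans <- setdiff(unique(conc$sample_id), meta$sample_id)
  if (length(orphans) > 0) {
    stop("sample(s) missing from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  structure(list(concentrations = conc, metadata = meta),
            class = "element_panel")
}

#' @export
print.element_panel <- function(x, ...) {
  n_samp <- length(unique(x$concentrations$sample_id))
  n_elem <- length(unique(x$concentrations$element))
  counts <- table(x$concentrations$status)
  cat("<element_panel> ", n_samp, " samples x ", n_elem, " elements\n",
      sep = "")
  cat("  quantified: ", counts["quantified"],
      "  below limit: ", counts["below_limit"],
      "  above range: ", counts["above_range"], "\n", sep = "")
  invisible(x)
}

#' Write a panel back to the wide cell format
#'
#' Inverse of [read_concentrations()] / [read_metadata()]: quantified
#' values are written as numbers, censored values as `"<limit"` and
#' above-range values as `"NR*"`, so that a written panel reloads with
#' every status and value intact.
#'
#' @param panel an `element_panel`.
#' @param conc_path,meta_path output CSV paths (`meta_path` optional).
#' @return `conc_path`, invisibly.
#' @export
write_panel <- function(panel, conc_path, meta_path = NULL) {
  conc <- panel$concentrations
  cell <- ifelse(conc$status == "quantified", format_plain(conc$value),
          ifelse(conc$status == "below_limit", paste0("<", format_plain(conc$limit)),
                 "NR*"))
  wide <- tidyr::pivot_wider(
    tibble::tibble(sample_id = conc$sample_id, element = conc$element, cell = cell),
    names_from = "element", values_from = "cell")
  readr::write_csv(wide, conc_path, na = "")
  if (!is.null(meta_path)) readr::write_csv(panel$metadata, meta_path, na = "")
  invisible(conc_path)
}

# Shortest decimal representation that reparses to the same double, so
# written panels reload bit-exactly.
format_plain <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in c(7, 15, 17)) {
      s <- format(v, digits = d, trim = TRUE, scientific = FALSE,
                  drop0trailing = TRUE)
      if (identical(suppressWarnings(as.numeric(s)), v)) return(s)
    }
    s
  }, character(1))
}

#' Resolve censored concentrations to numbers
#'
#' Turns status/value/limit triples into the single numeric concentration
#' that enters the intake equations, under a stated censoring policy:
#' `"zero"` substitutes 0 for below-limit results, `"half_limit"`
#' substitutes limit/2 and `"at_limit"` substitutes the limit itself.
#' Above-range results cannot be resolved to a number; they are returned
#' as `NA` (excluded) or raise an error, per `above_range_policy`.
#'
#' @param status,value,limit parallel vectors as in an `element_panel`
#'   concentration table.
#' @param policy one of `"zero"`, `"half_limit"`, `"at_limit"`.
#' @param above_range_policy `"exclude"` (default) or `"error"`.
#' @return numeric vector of resolved concentrations (ug/kg), `NA` for
#'   excluded above-range entries.
#' @examples
#' apply_censor_policy("below_limit", NA, 17.4, policy = "half_limit")
#' @export
apply_censor_policy <- function(status, value, limit,
                                policy = c("zero", "half_limit", "at_limit"),
                                above_range_policy = c("exclude", "error")) {
  policy <- match.arg(policy)
  above_range_policy <- match.arg(above_range_policy)
  if (above_range_policy == "error" && any(status == "above_range")) {
    stop("panel contains above-range (not quantifiable) results", call. = FALSE)
  }
  sub <- switch(policy,
    zero = 0 * limit,
    half_limit = limit / 2,
    at_limit = limit
  )
  out <- ifelse(status == "quantified", value,
         ifelse(status == "below_limit", sub, NA_real_))
  as.numeric(out)
}

#' Assessment configuration
#'
#' Bundles the exposure-scenario constants and data-handling policies used
#' by [assess_panel()].
#'
#' @param body_weight consumer body weight in kg (default 70, the standard
#'   adult reference weight).
#' @param servings_per_day default number of daily servings.
#' @param censor_policy substitution rule for below-limit results; see
#'   [apply_censor_policy()].
#' @param above_range_policy `"exclude"` or `"error"`.
#' @param cr_convention `"table_match"` (EDI divided by the slope-factor
#'   constant) or `"literal_eq5"` (EDI multiplied by the slope factor);
#'   see [compute_cr()].
#' @return list of class `assessment_config`.
#' @export
assessment_config <- function(body_weight = 70,
                              servings_per_day = 1L,
                              censor_policy = c("zero", "half_limit", "at_limit"),
                              above_range_policy = c("exclude", "error"),
                              cr_convention = c("table_match", "literal_eq5")) {
  stopifnot(body_weight > 0, servings_per_day >= 1)
  structure(list(
    body_weight = body_weight,
    servings_per_day = as.integer(servings_per_day),
    censor_policy = match.arg(censor_policy),
    above_range_policy = match.arg(above_range_policy),
    cr_convention = match.arg(cr_convention)
  ), class = "assessment_config")
}
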