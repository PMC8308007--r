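#' Specification for a synthetic instrument panel
#'
#' Describes the statistical structure of a simulated analytical run:
#' assumed true concentrations per element, the digestion/dilution
#' geometry, multiplicative instrument noise, and the censoring and
#' calibration limits that turn continuous readings into quantified,
#' below-limit or above-range records.
#'
#' Defaults emulate the packaged reference panel: true concentrations are
#' drawn log-uniformly between each element's observed minimum and maximum
#' (quantified) concentrations, reporting limits are the panel's censoring
#' limits, noise levels are each element's median replicate RSD from the
#' packaged QC recoveries, and the upper calibration limit is the top
#' calibration standard (50 ug/L in solution).
#'
#' @param n_samples number of samples to simulate.
#' @param elements chemical symbols to simulate; defaults to the 20
#'   elements reported in the reference panel.
#' @param ranges named list of `c(min, max)` true-concentration ranges in
#'   ug/kg; defaults derived from the reference panel.
#' @param loq_limits named vector of reporting limits, ug/kg (elements
#'   absent from the vector are never censored).
#' @param upper_calibration top calibration standard, ug/L in solution;
#'   solution readings above it become above-range records.
#' @param noise_rsd named vector of per-element relative standard
#'   deviations in percent; single unnamed value recycles to all elements.
#' @param dilution_factor,returned_volume_ml digestion geometry; the
#'   returned volume is a nominal value, recorded in generated metadata.
#' @param seed integer driving all randomness. Each element draws from its
#'   own seeded stream (keyed by the element's position in the 21-element
#'   panel), so adding or removing elements does not perturb the draws of
#'   the others.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n_samples = 36,
                           elements = NULL,
                           ranges = NULL,
                           loq_limits = default_loq_limits(),
                           upper_calibration = 50,
                           noise_rsd = NULL,
                           dilution_factor = 5,
                           returned_volume_ml = 10,
                           seed = 1L) {
  ref <- reference_panel()
  if (is.null(elements)) elements <- sort(unique(ref$concentrations$element))
  if (length(elements) == 0) stop("element set must not be empty", call. = FALSE)
  elements <- normalise_element(elements)

  if (is.null(ranges)) {
    q <- ref$concentrations[ref$concentrations$status == "quantified", ]
    q <- q[q$element %in% elements & q$value > 0, ]
    ranges <- lapply(split(q$value, q$element), range)
  }
  missing_rng <- setdiff(elements, names(ranges))
  if (length(missing_rng) > 0) {
    stop("no concentration range for: ", paste(missing_rng, collapse = ", "),
         call. = FALSE)
  }
  bad <- vapply(ranges, function(r) r[1] > r[2] || r[1] <= 0, logical(1))
  if (any(bad)) stop("ranges must have 0 < min <= max", call. = FALSE)

  if (is.null(noise_rsd)) {
    qc <- qc_recoveries()
    noise_rsd <- vapply(split(qc$rsd_percent, qc$element),
                        stats::median, numeric(1))
  } else if (is.null(names(noise_rsd))) {
    noise_rsd <- stats::setNames(rep(noise_rsd[1], length(elements)), elements)
  }
  rsd <- ifelse(elements %in% names(noise_rsd), noise_rsd[elements], 0)
  names(rsd) <- elements
  if (any(rsd < 0)) stop("noise_rsd must be non-negative", call. = FALSE)

  loq <- ifelse(elements %in% names(loq_limits), loq_limits[elements], 0)
  names(loq) <- elements
  if (any(loq < 0)) stop("loq_limits must be non-negative", call. = FALSE)

  structure(list(
    n_samples = as.integer(n_samples),
    elements = elements,
    ranges = ranges[elements],
    loq_limits = loq,
    upper_calibration = upper_calibration,
    noise_rsd = rsd,
    dilution_factor = dilution_factor,
    returned_volume_ml = returned_volume_ml,
    seed = as.integer(seed)
  ), class = "generator_spec")
}

# Independent seeded stream per (seed, key); keys 0..21 keep streams stable
# when the element subset changes.
stream_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 1009 + key * 7919) %% 2147483629)
}

with_stream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, key))
  expr
}

#' Generate a synthetic instrument panel
#'
#' Simulates the full sample flow: true element concentrations per sample,
#' the solution readings the instrument would see after digestion and
#' dilution (with multiplicative gaussian noise at per-element RSD,
#' truncated at zero), and the resulting concentration panel in which
#' back-calculated values below an element's reporting limit become
#' left-censored records and solution readings above the top calibration
#' standard become above-range records.
#'
#' Serving masses are drawn from the serving sizes observed in the
#' reference panel, digested masses uniformly over the observed 0.41-0.52 g
#' span, and the returned digest volume is the nominal value in the spec.
#' Identical seeds give identical output.
#'
#' @param spec a [generator_spec()].
#' @return list of class `synthetic_panel` with
#'   * `truth`: tibble `sample_id`, `element`, `true_conc` (ug/kg);
#'   * `readings`: instrument-level tibble (`c_inst_ug_per_L`, geometry);
#'   * `panel`: an `element_panel` ready for [assess_panel()].
#' @examples
#' sim <- generate_panel(generator_spec(n_samples = 6, seed = 42))
#' table(sim$panel$concentrations$status)
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_samples
  ids <- sprintf("S%02d", seq_len(n))

  ref_meta <- reference_panel()$metadata
  meta <- with_stream(spec$seed, 0, tibble::tibble(
    sample_id = ids,
    protein_type = sample(ref_meta$protein_type, n, replace = TRUE),
    serving_mass_g = sample(sort(unique(ref_meta$serving_mass_g)), n,
                            replace = TRUE),
    weighed_mass_g = round(stats::runif(n, 0.41, 0.52), 4),
    returned_volume_ml = spec$returned_volume_ml,
    volume_is_nominal = TRUE
  ))

  per_elem <- lapply(spec$elements, function(el) {
    key <- match(el, panel_elements)
    with_stream(spec$seed, key, {
      rng <- spec$ranges[[el]]
      true_conc <- exp(stats::runif(n, log(rng[1]), log(rng[2])))
      eps <- stats::rnorm(n)
      c_inst_clean <- forward_reading(true_conc, spec$dilution_factor,
                                      meta$returned_volume_ml,
                                      meta$weighed_mass_g)
      c_inst <- pmax(0, c_inst_clean * (1 + eps * spec$noise_rsd[el] / 100))
      tibble::tibble(sample_id = ids, element = el,
                     true_conc = true_conc, c_inst_ug_per_L = c_inst)
    })
  })
  draws <- dplyr::bind_rows(per_elem)

  readings <- dplyr::left_join(
    draws[, c("sample_id", "element", "c_inst_ug_per_L")],
    meta[, c("sample_id", "returned_volume_ml", "weighed_mass_g")],
    by = "sample_id")
  readings$df <- spec$dilution_factor
  readings <- readings[, c("sample_id", "element", "c_inst_ug_per_L", "df",
                           "returned_volume_ml", "weighed_mass_g")]

  back <- back_calculate(readings$c_inst_ug_per_L, readings$df,
                         readings$returned_volume_ml,
                         readings$weighed_mass_g)
  loq <- unname(spec$loq_limits[readings$element])
  above <- readings$c_inst_ug_per_L > spec$upper_calibration
  censored <- !above & back < loq

  conc <- tibble::tibble(
    sample_id = readings$sample_id,
    element = readings$element,
    status = ifelse(above, "above_range",
                    ifelse(censored, "below_limit", "quantified")),
    value = ifelse(!above & !censored, back, NA_real_),
    limit = ifelse(censored, as.numeric(loq), NA_real_)
  )

  structure(list(
    truth = draws[, c("sample_id", "element", "true_conc")],
    readings = readings,
    panel = load_panel(conc, meta)
  ), class = "synthetic_panel")
}

#' Write a synthetic panel to disk
#'
#' Writes `panel.csv`, `meta.csv`, `readings.csv` and `truth.csv` in the
#' formats the loaders of this package read.
#'
#' @param sim a `synthetic_panel` from [generate_panel()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(sim$panel, file.path(dir, "panel.csv"),
              file.path(dir, "meta.csv"))
  readr::write_csv(sim$readings, file.path(dir, "readings.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
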