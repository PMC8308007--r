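#' Percent recovery of a control sample
#'
#' @param measured_mean mean measured concentration, ug/L.
#' @param expected nominal (spiked or certified) concentration, ug/L.
#' @return recovery in percent: 100 x measured / expected.
#' @examples
#' recovery_percent(0.952, 1.0)
#' @export
recovery_percent <- function(measured_mean, expected) {
  if (any(expected <= 0)) stop("expected concentration must be positive",
                               call. = FALSE)
  100 * measured_mean / expected
}

#' Acceptance verdict for a recovery
#'
#' Compares a percent recovery against an inclusive acceptance band:
#' 75--125% is the conventional band for matrix-spiked controls
#' ("100 +/- 25%"), 80--120% for certified reference materials
#' ("100 +/- 20%"). Band endpoints count as passes.
#'
#' @param recovery percent recovery (see [recovery_percent()]).
#' @param band numeric length-2 `(low, high)` acceptance interval in
#'   percent; defaults to the matrix-spike band `c(75, 125)`.
#' @return character vector, `"pass"` or `"fail"`.
#' @examples
#' recovery_verdict(123.2)                  # pass at 75-125
#' recovery_verdict(123.2, band = c(80, 120)) # fail at the CRM band
#' @export
recovery_verdict <- function(recovery, band = c(75, 125)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  ifelse(recovery >= band[1] & recovery <= band[2], "pass", "fail")
}

#' Batch QC verdict table
#'
#' Applies [recovery_verdict()] to a table of control recoveries, e.g.
#' the packaged [qc_recoveries()] fixture, yielding a per-control verdict.
#'
#' @param controls tibble with at least `element` and `rec_percent`.
#' @param band acceptance band, as in [recovery_verdict()].
#' @return the input with a `verdict` column appended.
#' @export
qc_verdicts <- function(controls, band = c(75, 125)) {
  if (!"rec_percent" %in% names(controls)) {
    stop("controls table needs a rec_percent column", call. = FALSE)
  }
  controls$verdict <- recovery_verdict(controls$rec_percent, band)
  controls
}

#' Resolution transmission and sensitivity gates
#'
#' Instrument-health check for a sector-field instrument: the ratio of ion
#' intensities between resolution modes must sit inside the expected
#' transmission windows (medium/low 10--12%, high/low 1--2%), and the
#' low-resolution intensity of the reference isotope must reach a minimum
#' count rate for the instrument to be deemed sufficiently sensitive.
#'
#' @param lr_intensity,mr_intensity,hr_intensity ion intensities (cps) of
#'   the reference isotope in low, medium and high resolution.
#' @param min_lr_cps sensitivity floor on the low-resolution intensity
#'   (default 100000 cps).
#' @param mr_band,hr_band inclusive transmission windows in percent.
#' @param tol widening applied to both ends of each window (percentage
#'   points, default 0: the windows are hard bounds).
#' @return A one-row tibble with the transmission percentages and the
#'   `transmission` and `sensitivity` verdicts (`"pass"`/`"fail"`).
#' @examples
#' transmission_check(1e6, 1.1e5, 1.5e4)
#' @export
transmission_check <- function(lr_intensity, mr_intensity, hr_intensity,
                               min_lr_cps = 1e5,
                               mr_band = c(10, 12), hr_band = c(1, 2),
                               tol = 0) {
  if (any(c(lr_intensity, mr_intensity, hr_intensity) < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (lr_intensity == 0) stop("LR intensity must be positive", call. = FALSE)
  mr_over_lr <- 100 * mr_intensity / lr_intensity
  hr_over_lr <- 100 * hr_intensity / lr_intensity
  in_band <- function(x, b) x >= b[1] - tol & x <= b[2] + tol
  tibble::tibble(
    lr_intensity = lr_intensity,
    mr_over_lr = mr_over_lr,
    hr_over_lr = hr_over_lr,
    transmission = ifelse(in_band(mr_over_lr, mr_band) &
                            in_band(hr_over_lr, hr_band), "pass", "fail"),
    sensitivity = ifelse(lr_intensity >= min_lr_cps, "pass", "fail")
  )
}
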