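#' Fit an internal-standard ratio calibration curve
#'
#' Ordinary least squares of the analyte/IS peak-area ratio on nominal
#' concentration, the standard quantification model for internal-standard
#' HPLC assays. Unweighted by default; `1/x^2` weighting (common when the
#' calibrated range spans several orders of magnitude) is available but
#' off unless requested.
#'
#' @param levels A data frame with columns `concentration` (ug/mL),
#'   `analyte_area` and `is_area` - one row per calibration level.
#' @param analyte_id Label stored on the curve.
#' @param weighting `"none"` (default) or `"1/x2"`.
#'
#' @return An object of class `"calibration_curve"`: a list with `slope`,
#'   `intercept`, `r_squared`, `range_low`, `range_high`, `n_levels`,
#'   `analyte_id`, `weighting`.
#' @examples
#' lv <- data.frame(concentration = c(0.25, 0.5, 1, 2),
#'                  analyte_area = c(0.095, 0.19, 0.38, 0.76),
#'                  is_area = 1)
#' fit_calibration(lv, analyte_id = "CLP")
#' @export
fit_calibration <- function(levels, analyte_id = "analyte",
                            weighting = c("none", "1/x2")) {
  weighting <- match.arg(weighting)
  need <- c("concentration", "analyte_area", "is_area")
  if (!all(need %in% names(levels)))
    stopf("`levels` must have columns %s", paste(need, collapse = ", "))
  if (any(levels$is_area <= 0))
    stopf("invalid ratio: all internal-standard areas must be > 0")
  x <- levels$concentration
  if (length(unique(x)) < 2L)
    stopf("insufficient data: at least 2 distinct concentrations are required")
  y <- levels$analyte_area / levels$is_area
  w <- if (weighting == "1/x2") {
    if (any(x <= 0)) stopf("1/x2 weighting requires strictly positive concentrations")
    1 / x^2
  } else NULL
  fit <- lm(y ~ x, weights = w)
  cf <- coef(fit)
  # suppress summary.lm's note on residuals at machine precision: exact
  # linear input is a legitimate (and tested) case here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(analyte_id = analyte_id,
                 slope = unname(cf[2L]),
                 intercept = unname(cf[1L]),
                 r_squared = r2,
                 range_low = min(x), range_high = max(x),
                 n_levels = length(unique(x)),
                 weighting = weighting),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [%s]: ratio = %.4g * conc %+.4g (r^2 = %.6f)\n",
              x$analyte_id, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  range %g - %g ug/mL over %d levels (%s weighting)\n",
              x$range_low, x$range_high, x$n_levels, x$weighting))
  invisible(x)
}

#' Predicted area ratio at a concentration
#'
#' @param object A [fit_calibration()] curve.
#' @param concentration Concentration(s), ug/mL.
#' @param ... Unused.
#' @return Predicted analyte/IS area ratio(s).
#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration
}

#' Back-calculate concentration from an area ratio
#'
#' Inverts the calibration line: `(ratio - intercept) / slope`. Ratios that
#' back-calculate outside the calibrated range are returned, not rejected,
#' with the `"out_of_range"` attribute set - the downstream LLOQ censoring
#' rule decides what to do with them.
#'
#' @param curve A [fit_calibration()] curve.
#' @param ratio Observed analyte/IS area ratio(s).
#' @return Concentration(s), ug/mL, with logical attribute `out_of_range`.
#' @export
back_calculate <- function(curve, ratio) {
  if (!inherits(curve, "calibration_curve")) stopf("`curve` must be a calibration_curve")
  if (curve$slope == 0) stopf("degenerate curve: zero slope")
  conc <- (ratio - curve$intercept) / curve$slope
  attr(conc, "out_of_range") <- conc < curve$range_low | conc > curve$range_high
  conc
}

#' Estimate LOD and LLOQ from signal-to-noise
#'
#' With the package's peak-to-peak noise convention `S/N = 2 h / N_pp` and
#' a linear height response `h = s c`, the concentration at which the
#' predicted S/N reaches 3 (detection) or 10 (quantification) is
#' `c = SN * N_pp / (2 s)`. The height-response slope (not the area slope)
#' is used because S/N is a height quantity.
#'
#' @param height_response_slope Peak height per unit concentration
#'   (response units per ug/mL), > 0.
#' @param noise_excursion Peak-to-peak baseline excursion in an
#'   analyte-free region, response units, > 0.
#' @return A list of class `"sensitivity_limits"` with `lod` and `lloq`
#'   (ug/mL). Their ratio is 10/3 by construction.
#' @examples
#' estimate_limits(height_response_slope = 1000, noise_excursion = 2)
#' @export
estimate_limits <- function(height_response_slope, noise_excursion) {
  check_scalar(height_response_slope, "height_response_slope", positive = TRUE)
  check_scalar(noise_excursion, "noise_excursion", positive = TRUE)
  structure(list(lod = 3 * noise_excursion / (2 * height_response_slope),
                 lloq = 10 * noise_excursion / (2 * height_response_slope)),
            class = "sensitivity_limits")
}
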