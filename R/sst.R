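#' System-suitability limits
#'
#' Default acceptance limits of the assay: resolution strictly greater than
#' 2.0, tailing factor at most 2.0, plate count strictly greater than 2000.
#'
#' @param rs_min Minimum resolution (exclusive bound).
#' @param t_max Maximum tailing factor (inclusive bound).
#' @param n_min Minimum plate count (exclusive bound).
#' @return A named list of limits.
#' @export
sst_limits <- function(rs_min = 2.0, t_max = 2.0, n_min = 2000) {
  check_scalar(rs_min, "rs_min", positive = TRUE)
  check_scalar(t_max, "t_max", positive = TRUE)
  check_scalar(n_min, "n_min", positive = TRUE)
  list(rs_min = rs_min, t_max = t_max, n_min = n_min)
}

#' Column efficiency (theoretical plate count)
#'
#' Half-height convention: `N = 5.54 (tR / w0.5)^2`, with `w0.5` the peak
#' width at 50% of baseline-corrected height.
#'
#' @param peak One row of [detect_peaks()] output (or any list with
#'   `retention_time` and `width_at_half`).
#' @return Plate count, dimensionless.
#' @export
plate_count <- function(peak) {
  w <- peak$width_at_half
  if (is.null(w) || !is.finite(w) || w <= 0)
    stopf("degenerate peak: width at half height must be > 0")
  5.54 * (peak$retention_time / w)^2
}

#' Tailing factor (USP convention)
#'
#' `T = w0.05 / (2 f0.05)`, where `w0.05` is the full width at 5% of height
#' and `f0.05` the distance from the leading edge at 5% height to the apex.
#' A symmetric peak gives `T = 1`; tailing gives `T > 1`.
#'
#' @inheritParams plate_count
#' @return Tailing factor, dimensionless.
#' @export
tailing_factor <- function(peak) {
  f <- peak$front_at_5pct
  if (is.null(f) || !is.finite(f) || f <= 0)
    stopf("degenerate peak: front half-width at 5%% height must be > 0")
  peak$width_at_5pct / (2 * f)
}

#' Resolution between two adjacent peaks
#'
#' Baseline-width convention `Rs = 2 (tR2 - tR1) / (Wb1 + Wb2)`, with the
#' base width taken as `Wb = 1.699 w0.5` (the Gaussian relation between the
#' 4-sigma base width and the half-height width).
#'
#' @param peak1,peak2 Peak measurements with `peak2` eluting at or after
#'   `peak1`.
#' @return Resolution, dimensionless. Identical retention times return 0
#'   with a co-elution warning.
#' @export
resolution <- function(peak1, peak2) {
  if (peak2$retention_time < peak1$retention_time)
    stopf("`peak2` must elute at or after `peak1`")
  if (peak2$retention_time == peak1$retention_time) {
    warnf("co-eluting peaks (identical retention times); Rs = 0")
    return(0)
  }
  wb1 <- 1.699 * peak1$width_at_half
  wb2 <- 1.699 * peak2$width_at_half
  2 * (peak2$retention_time - peak1$retention_time) / (wb1 + wb2)
}

#' Signal-to-noise ratio of a peak
#'
#' `S/N = 2 h / N_pp`, where `h` is the baseline-corrected peak height and
#' `N_pp` the peak-to-peak excursion of the signal in an analyte-free blank
#' region after linear detrending - the classical pharmacopeial definition.
#'
#' @inheritParams plate_count
#' @param chrom The [chromatogram()] the peak was measured on.
#' @param blank_region `c(lower, upper)` time window in minutes containing
#'   baseline only; must cover at least 20 samples.
#' @return Signal-to-noise ratio, dimensionless.
#' @export
signal_to_noise <- function(peak, chrom, blank_region) {
  if (length(blank_region) != 2L || blank_region[2] <= blank_region[1])
    stopf("`blank_region` must be c(lower, upper) with lower < upper")
  idx <- chrom$time >= blank_region[1] & chrom$time <= blank_region[2]
  if (sum(idx) < 20L)
    stopf("blank region holds %d samples; at least 20 are required", sum(idx))
  fit <- lm(signal ~ time, data = chrom[idx, ])
  pp <- diff(range(resid(fit)))
  if (pp <= .Machine$double.eps^0.5 * max(1, diff(range(chrom$signal))))
    stopf("zero noise in blank region: S/N is undefined")
  2 * peak$height / pp
}

#' Evaluate system suitability for a set of peaks
#'
#' Computes plate count, tailing factor and resolution to the preceding
#' peak for each analyte and flags each metric against the limits. Pass
#' semantics follow the limit statements exactly: `Rs > rs_min` and
#' `N > n_min` are strict, `T <= t_max` is inclusive.
#'
#' @param peaks A `peak_measurements` data frame ordered by retention time
#'   (as returned by [detect_peaks()]).
#' @param limits Limits from [sst_limits()].
#' @return A `data.frame` of class `"sst_report"` with one row per analyte:
#'   `analyte_id`, `retention_time`, `plate_count`, `tailing_factor`,
#'   `resolution` (NA for the first peak), the three pass flags, and an
#'   overall `pass`. With a single peak the resolution column is `NA` and a
#'   warning is raised.
#' @export
sst_evaluate <- function(peaks, limits = sst_limits()) {
  if (nrow(peaks) == 0L) stopf("no peaks to evaluate")
  if (is.unsorted(peaks$retention_time, strictly = FALSE))
    stopf("`peaks` must be ordered by retention time")
  if (nrow(peaks) < 2L)
    warnf("only one peak supplied; resolution cannot be computed")
  n <- nrow(peaks)
  N <- vapply(seq_len(n), function(i) plate_count(peaks[i, ]), numeric(1))
  Tf <- vapply(seq_len(n), function(i) tailing_factor(peaks[i, ]), numeric(1))
  Rs <- rep(NA_real_, n)
  if (n >= 2L) {
    for (i in 2:n) Rs[i] <- resolution(peaks[i - 1L, ], peaks[i, ])
  }
  out <- data.frame(
    analyte_id = peaks$analyte_id,
    retention_time = peaks$retention_time,
    plate_count = N,
    tailing_factor = Tf,
    resolution = Rs,
    n_pass = N > limits$n_min,
    t_pass = Tf <= limits$t_max,
    rs_pass = ifelse(is.na(Rs), NA, Rs > limits$rs_min)
  )
  out$pass <- out$n_pass & out$t_pass & (is.na(out$rs_pass) | out$rs_pass)
  attr(out, "limits") <- limits
  class(out) <- c("sst_report", "data.frame")
  out
}
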