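#' Specify one chromatographic peak
#'
#' @param analyte_id Label for the analyte carried by this peak.
#' @param retention_time Apex retention time, minutes (> 0).
#' @param area Integrated peak area in response x minutes (>= 0). The
#'   detector response scale is arbitrary; only ratios and widths matter
#'   downstream.
#' @param sigma Gaussian width, minutes (> 0).
#' @param tau Exponential tail time constant, minutes; 0 gives a symmetric
#'   Gaussian, larger values an exponentially modified Gaussian (EMG) with
#'   tailing factor above 1.
#'
#' @return A list of class `"peak_spec"`.
#' @seealso [generate_chromatogram()], [default_peaks()]
#' @export
peak_spec <- function(analyte_id, retention_time, area = 1,
                      sigma = 0.08, tau = 0) {
  check_scalar(retention_time, "retention_time", positive = TRUE)
  check_scalar(area, "area", nonnegative = TRUE)
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(tau, "tau", nonnegative = TRUE)
  structure(list(analyte_id = as.character(analyte_id),
                 retention_time = retention_time,
                 area = area, sigma = sigma, tau = tau),
            class = "peak_spec")
}

#' Default four-peak system
#'
#' The bundled default peak table mirrors the elution order of the
#' clopidogrel assay this package accompanies: carboxylic acid metabolite
#' (CCA), atorvastatin (ATV), ibuprofen internal standard (IS), clopidogrel
#' (CLP), at retention times 9.663, 10.998, 11.802 and 12.682 min on a
#' 20-minute run. Widths are set so plate counts land in the 10^4 range of a
#' well-packed 250 mm column and the CLP peak carries a visible exponential
#' tail.
#'
#' @return A list of [peak_spec()] objects.
#' @export
default_peaks <- function() {
  list(
    peak_spec("CCA", 9.663, area = 4, sigma = 0.080, tau = 0),
    peak_spec("ATV", 10.998, area = 3, sigma = 0.085, tau = 0.062),
    peak_spec("IS", 11.802, area = 6, sigma = 0.090, tau = 0),
    peak_spec("CLP", 12.682, area = 5, sigma = 0.060, tau = 0.100)
  )
}

# Exponentially modified Gaussian density (unit area), numerically stable.
# For u = (sigma/tau - (t-mu)/sigma)/sqrt(2) the textbook form
#   f = exp(sigma^2/(2 tau^2) - (t-mu)/tau) erfc(u) / (2 tau)
# overflows when tau << sigma; rewriting with the scaled complement
# erfcx(u) = exp(u^2) erfc(u) gives
#   f = erfcx(u) exp(-(t-mu)^2 / (2 sigma^2)) / (2 tau),
# exact and stable for u >= 0 and moderate negative u. Far in the right
# tail (u << 0, where erfcx overflows) erfc(u) ~ 2 and the direct form's
# exponent is strongly negative, so the direct form is safe there.
# scaled complementary error function; pracma's loses accuracy above ~26,
# where the standard asymptotic series 1/(x sqrt(pi)) (1 - 1/(2x^2) + ...)
# is already accurate to ~1e-10
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  big <- x > 20
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    v <- 1 / (2 * x[big]^2)
    out[big] <- (1 - v * (1 - 3 * v * (1 - 5 * v))) / (x[big] * sqrt(pi))
  }
  out
}

# location of the EMG maximum relative to the Gaussian centre mu
# (0 for the symmetric case; in (0, tau) otherwise, found numerically)
emg_mode_offset <- function(sigma, tau) {
  if (tau < sigma * 1e-8) return(0)
  stats::optimize(function(x) emg_density(x, 0, sigma, tau),
                  interval = c(0, sigma + tau), maximum = TRUE,
                  tol = 1e-10)$maximum
}

emg_density <- function(t, mu, sigma, tau) {
  if (tau < sigma * 1e-8) {
    return(stats::dnorm(t, mean = mu, sd = sigma))
  }
  u <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  f <- numeric(length(t))
  ok <- u > -4
  if (any(ok)) {
    f[ok] <- erfcx_stable(u[ok]) *
      exp(-(t[ok] - mu)^2 / (2 * sigma^2)) / (2 * tau)
  }
  if (any(!ok)) {
    f[!ok] <- pracma::erfc(u[!ok]) *
      exp(sigma^2 / (2 * tau^2) - (t[!ok] - mu) / tau) / (2 * tau)
  }
  f
}

#' Construct a chromatogram object
#'
#' @param time Time axis, minutes, strictly increasing, length >= 2.
#' @param signal Detector response, same length as `time`.
#' @return A `data.frame` of class `"chromatogram"` with columns `time` and
#'   `signal`.
#' @export
chromatogram <- function(time, signal) {
  if (length(time) != length(signal)) stopf("`time`/`signal` length mismatch")
  if (length(time) < 2) stopf("a chromatogram needs at least 2 samples")
  if (any(diff(time) <= 0)) stopf("`time` must be strictly increasing")
  out <- data.frame(time = as.numeric(time), signal = as.numeric(signal))
  class(out) <- c("chromatogram", "data.frame")
  out
}

#' Simulate a multi-peak chromatogram
#'
#' Builds a detector trace as a sum of (exponentially modified) Gaussian
#' peaks plus additive Gaussian baseline noise. Each peak integrates to its
#' specified area (response x minutes) in the noiseless limit, which is the
#' property the peak-integration code is tested against.
#'
#' @param peaks A [peak_spec()] or list of them. Defaults to the bundled
#'   four-analyte system of [default_peaks()].
#' @param duration Run length, minutes. Every retention time must lie
#'   strictly inside `(0, duration)`.
#' @param sampling_rate Detector sampling rate in Hz (points per second).
#' @param baseline_noise_sd Standard deviation of the additive Gaussian
#'   baseline noise, response units (0 = noiseless).
#' @param seed Integer seed; required when `baseline_noise_sd > 0`.
#'
#' @return A [chromatogram()] with the generating peak list stored in the
#'   `"peaks"` attribute.
#' @examples
#' ch <- generate_chromatogram(peak_spec("X", 10, area = 5, sigma = 0.1),
#'                             duration = 20)
#' @export
generate_chromatogram <- function(peaks = default_peaks(), duration = 20,
                                  sampling_rate = 5, baseline_noise_sd = 0,
                                  seed = NULL) {
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  if (!is.list(peaks) || !all(vapply(peaks, inherits, TRUE, "peak_spec")))
    stopf("`peaks` must be a peak_spec or a list of peak_spec objects")
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar(baseline_noise_sd, "baseline_noise_sd", nonnegative = TRUE)
  for (p in peaks) {
    if (p$retention_time <= 0 || p$retention_time >= duration)
      stopf("peak '%s' at %.3f min lies outside the run (0, %g)",
            p$analyte_id, p$retention_time, duration)
  }
  dt <- 1 / (60 * sampling_rate)  # minutes per sample
  time <- seq(0, duration, by = dt)
  signal <- numeric(length(time))
  for (p in peaks) {
    # the EMG mode sits right of its Gaussian centre; shift the centre so
    # the observed apex lands at the specified retention time
    mu <- p$retention_time - emg_mode_offset(p$sigma, p$tau)
    signal <- signal + p$area * emg_density(time, mu, p$sigma, p$tau)
  }
  if (baseline_noise_sd > 0) {
    if (is.null(seed)) stopf("`seed` is required when baseline_noise_sd > 0")
    signal <- signal +
      withr::with_seed(seed, rnorm(length(time), sd = baseline_noise_sd))
  }
  out <- chromatogram(time, signal)
  attr(out, "peaks") <- peaks
  out
}
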