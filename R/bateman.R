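#' One-compartment oral plasma concentration (Bateman function)
#'
#' Closed-form solution of the one-compartment model with first-order
#' absorption and first-order elimination,
#' \deqn{C_p(t) = A\,(e^{-K_e t} - e^{-K_a t}),}
#' where `A = F D K_a / (V (K_a - K_e))` lumps bioavailability, dose and
#' volume of distribution into a single pre-exponential coefficient in
#' concentration units.
#'
#' @param t Time after dose, hours. Vectorised; all values must be >= 0.
#' @param A Pre-exponential coefficient, ug/mL. Must be > 0.
#' @param ka First-order absorption rate constant, 1/h. Must be > 0.
#' @param ke First-order elimination rate constant, 1/h. Must be > 0.
#'
#' @details The degenerate case `ka == ke` (where the solution changes
#' functional form to `A' t e^{-k t}`) is refused with an error rather than
#' silently substituted; callers simulating near-degenerate kinetics should
#' perturb one rate.
#'
#' @return Plasma concentration(s) in ug/mL, same length as `t`.
#' Non-negative whenever `ka > ke`.
#' @seealso [generate_profile()], [tmax_model()]
#' @examples
#' bateman_concentration(c(0, 1, 6), A = 10, ka = 1.5, ke = 0.15)
#' @export
bateman_concentration <- function(t, A, ka, ke) {
  check_scalar(A, "A", positive = TRUE)
  check_scalar(ka, "ka", positive = TRUE)
  check_scalar(ke, "ke", positive = TRUE)
  if (ka == ke)
    stopf("degenerate model: ka == ke (%g); the biexponential form is invalid", ka)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stopf("`t` must be finite and >= 0")
  A * (exp(-ke * t) - exp(-ka * t))
}

#' Construct a concentration-time profile
#'
#' Container for one subject x analyte series of plasma concentrations with
#' the metadata the downstream pharmacokinetic fits need (LLOQ, censoring
#' flags, dose). Normally produced by [generate_profile()] or
#' [read_profile()].
#'
#' @param time Sampling times in hours, strictly increasing.
#' @param concentration Measured concentrations, ug/mL, `>= 0`.
#' @param censored Logical flags marking below-LLOQ points. Default:
#'   `concentration < lloq`.
#' @param lloq Lower limit of quantification, ug/mL.
#' @param analyte_id,subject_id Labels.
#' @param dose_mg Administered dose, mg (may be `NA`).
#' @param true_params Optional list with elements `A`, `ka`, `ke` recording
#'   simulation ground truth.
#'
#' @return A `data.frame` of class `"conc_profile"` with columns `time`,
#'   `concentration`, `censored` and the metadata stored as attributes.
#' @export
conc_profile <- function(time, concentration, censored = NULL, lloq = 0,
                         analyte_id = "analyte", subject_id = "subject",
                         dose_mg = NA_real_, true_params = NULL) {
  if (length(time) != length(concentration))
    stopf("`time` and `concentration` must have equal length")
  if (any(diff(time) <= 0)) stopf("`time` must be strictly increasing")
  if (any(time < 0)) stopf("`time` must be >= 0")
  if (any(concentration < 0)) stopf("concentrations must be >= 0")
  check_scalar(lloq, "lloq", nonnegative = TRUE)
  if (is.null(censored)) censored <- concentration < lloq
  if (length(censored) != length(time)) stopf("`censored` has wrong length")
  out <- data.frame(time = as.numeric(time),
                    concentration = as.numeric(concentration),
                    censored = as.logical(censored))
  attr(out, "lloq") <- lloq
  attr(out, "analyte_id") <- analyte_id
  attr(out, "subject_id") <- subject_id
  attr(out, "dose_mg") <- dose_mg
  attr(out, "true_params") <- true_params
  class(out) <- c("conc_profile", "data.frame")
  out
}

#' Simulate a plasma concentration-time profile
#'
#' Samples the Bateman curve at a clinical schedule, applies multiplicative
#' lognormal assay noise, and censors values below the LLOQ. Censored points
#' are retained in the record but flagged, so downstream fits can exclude
#' them while the raw series stays intact.
#'
#' @inheritParams bateman_concentration
#' @param times Sampling times, hours, strictly increasing. Default is the
#'   clinical schedule used throughout the package: predose plus 0.25, 0.5,
#'   1, 3, 6, 9 and 12 h.
#' @param lloq Lower limit of quantification, ug/mL; simulated values below
#'   it are flagged `censored`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   assay error (0 = noiseless). The lognormal keeps concentrations
#'   positive and its parameters are chosen so the multiplicative factor has
#'   mean 1 and the requested CV.
#' @param seed Integer seed; required whenever `noise_cv > 0`. Randomness is
#'   scoped to this call (no global RNG state is touched).
#' @param analyte_id,subject_id,dose_mg Metadata passed to [conc_profile()].
#'
#' @return A [conc_profile()] whose `true_params` attribute records the
#'   generating `A`, `ka`, `ke`.
#' @examples
#' p <- generate_profile(A = 5.1, ka = 3.2, ke = 0.15, noise_cv = 0.05, seed = 7)
#' p$concentration
#' @export
generate_profile <- function(A, ka, ke,
                             times = c(0, 0.25, 0.5, 1, 3, 6, 9, 12),
                             lloq = 0, noise_cv = 0, seed = NULL,
                             analyte_id = "analyte", subject_id = "subject",
                             dose_mg = NA_real_) {
  check_scalar(noise_cv, "noise_cv", nonnegative = TRUE)
  conc <- bateman_concentration(times, A, ka, ke)
  if (noise_cv > 0) {
    if (is.null(seed)) stopf("`seed` is required when noise_cv > 0")
    sdlog <- sqrt(log1p(noise_cv^2))
    mult <- withr::with_seed(seed,
      rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    conc <- conc * mult
  }
  conc_profile(times, conc, lloq = lloq, analyte_id = analyte_id,
               subject_id = subject_id, dose_mg = dose_mg,
               true_params = list(A = A, ka = ka, ke = ke))
}

#' Simulate quality-control replicate measurements
#'
#' Draws `n` back-calculated concentrations about `nominal * true_recovery`
#' with multiplicative lognormal error, emulating replicate QC injections at
#' one spiking level.
#'
#' @param nominal Nominal (spiked) concentration, ug/mL.
#' @param true_recovery True recovery fraction of the simulated method
#'   (1 = unbiased).
#' @param cv Coefficient of variation of the replicate error (0 = exact).
#' @param n Number of replicates.
#' @param seed Integer seed; required when `cv > 0`.
#'
#' @return Numeric vector of `n` measured concentrations.
#' @examples
#' generate_qc_replicates(0.25, true_recovery = 0.96, cv = 0.04, n = 3, seed = 1)
#' @export
generate_qc_replicates <- function(nominal, true_recovery = 1, cv = 0,
                                   n = 3, seed = NULL) {
  check_scalar(nominal, "nominal", positive = TRUE)
  check_scalar(true_recovery, "true_recovery", positive = TRUE)
  check_scalar(cv, "cv", nonnegative = TRUE)
  if (!is.numeric(n) || n < 1) stopf("`n` must be >= 1")
  centre <- nominal * true_recovery
  if (cv == 0) return(rep(centre, n))
  if (is.null(seed)) stopf("`seed` is required when cv > 0")
  sdlog <- sqrt(log1p(cv^2))
  withr::with_seed(seed,
    centre * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
}
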