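# quantifiable points: uncensored and strictly positive (log fits need > 0)
quantifiable <- function(profile) {
  !profile$censored & profile$concentration > 0
}

#' Terminal elimination rate constant from the log-linear tail
#'
#' Fits ordinary least squares of `log10(Cp)` on time over the terminal
#' points and converts the slope with `Ke = -ln(10) * slope` (the classical
#' "-Ke/2.303" relation, using the exact base-10 log factor). The intercept
#' is retained for back-extrapolation by the method of residuals.
#'
#' @param profile A [conc_profile()].
#' @param rule Terminal-point selection. `"after_tmax"` (default): all
#'   quantifiable points strictly after the observed Cmax - deterministic
#'   and reproducible. `"best_r2"`: among terminal suffixes of length >= 3
#'   of the post-Cmax points, the one maximising adjusted r-squared.
#' @param min_points Minimum number of terminal points (default 3).
#'
#' @return A list of class `"terminal_fit"`: `ke` (1/h), `intercept`
#'   (log10 scale), `slope`, `r_squared`, `n_points`, `times`.
#' @examples
#' p <- generate_profile(A = 10, ka = 1.5, ke = 0.15)
#' terminal_ke(p)
#' @export
terminal_ke <- function(profile, rule = c("after_tmax", "best_r2"),
                        min_points = 3L) {
  rule <- match.arg(rule)
  ok <- quantifiable(profile)
  if (!any(ok)) stopf("no quantifiable points in profile")
  tq <- profile$time[ok]
  cq <- profile$concentration[ok]
  t_cmax <- tq[which.max(cq)]
  term <- tq > t_cmax
  if (sum(term) < min_points)
    stopf("only %d quantifiable points after the observed Cmax; %d required",
          sum(term), min_points)
  tt <- tq[term]
  cc <- cq[term]

  fit_span <- function(i) {
    f <- lm(log10(cc[i:length(cc)]) ~ tt[i:length(tt)])
    sm <- suppressWarnings(summary(f))  # exact log-linear data is legitimate
    list(slope = unname(coef(f)[2L]), intercept = unname(coef(f)[1L]),
         r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
         n = length(cc) - i + 1L, times = tt[i:length(tt)])
  }
  if (rule == "after_tmax") {
    best <- fit_span(1L)
  } else {
    starts <- seq_len(length(cc) - min_points + 1L)
    fits <- lapply(starts, fit_span)
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "adj_r2"))]]
  }
  if (best$slope >= 0)
    stopf("no elimination phase: terminal slope is non-negative")
  structure(list(ke = -log(10) * best$slope, intercept = best$intercept,
                 slope = best$slope, r_squared = best$r2,
                 n_points = best$n, times = best$times),
            class = "terminal_fit")
}

#' Absorption rate constant by the method of residuals
#'
#' Back-extrapolates the terminal line into the absorption phase and fits
#' the log-linear decay of the residuals
#' `r(t) = 10^(intercept + slope t) - Cp(t)` at the quantifiable points at
#' or before the observed Cmax; `Ka = -ln(10) * slope(log10 r ~ t)`.
#' For a one-compartment curve with an exact terminal line the residuals
#' are exactly `A exp(-Ka t)`, so the fit recovers Ka.
#'
#' @param profile A [conc_profile()].
#' @param terminal_fit The [terminal_ke()] fit of the same profile.
#' @return Ka in 1/h, with attributes `n_points` and `r_squared`.
#' @export
method_of_residuals <- function(profile, terminal_fit) {
  if (!inherits(terminal_fit, "terminal_fit"))
    stopf("`terminal_fit` must come from terminal_ke()")
  ok <- !profile$censored
  tq <- profile$time[ok]
  cq <- profile$concentration[ok]
  pos <- cq > 0
  t_cmax <- if (any(pos)) tq[pos][which.max(cq[pos])] else
    stopf("no positive concentrations in profile")
  absn <- tq <= t_cmax
  if (sum(absn) < 2L)
    stopf("fewer than 2 quantifiable points in the absorption phase")
  ta <- tq[absn]
  pred <- 10^(terminal_fit$intercept + terminal_fit$slope * ta)
  r <- pred - cq[absn]
  if (any(r <= 0))
    stopf(paste("non-positive residual in the absorption phase:",
                "observed concentrations exceed the back-extrapolated line",
                "(no distinct absorption phase or model violation)"))
  f <- lm(log10(r) ~ ta)
  slope <- unname(coef(f)[2L])
  if (slope >= 0)
    stopf("residuals do not decay: absorption rate is not identifiable")
  ka <- -log(10) * slope
  attr(ka, "n_points") <- length(ta)
  attr(ka, "r_squared") <- suppressWarnings(summary(f)$r.squared)
  ka
}

#' Elimination half-life
#'
#' @param ke Elimination rate constant, 1/h, > 0.
#' @return `ln(2) / ke`, hours.
#' @export
half_life <- function(ke) {
  if (any(!is.finite(ke)) || any(ke <= 0)) stopf("`ke` must be > 0")
  log(2) / ke
}

#' Model-predicted time of maximum concentration
#'
#' Setting `dCp/dt = 0` for the one-compartment oral model gives
#' `tmax = ln(ka/ke) / (ka - ke)`.
#'
#' @param ka,ke Absorption and elimination rate constants, 1/h, both > 0
#'   and distinct. The degenerate limit `ka -> ke` tends to `1/ke` but the
#'   degenerate case itself is an error, consistent with
#'   [bateman_concentration()].
#' @return tmax in hours.
#' @export
tmax_model <- function(ka, ke) {
  check_scalar(ka, "ka", positive = TRUE)
  check_scalar(ke, "ke", positive = TRUE)
  if (ka == ke)
    stopf("degenerate model: ka == ke (limit would be 1/ke = %g h)", 1 / ke)
  log(ka / ke) / (ka - ke)
}

#' Linear trapezoidal AUC to the last quantifiable time
#'
#' @param profile A [conc_profile()]; censored points are excluded, so the
#'   integral runs from the first to the last quantifiable sampling time.
#' @return AUC(0-t) in ug.h/mL.
#' @export
auc_trapezoid <- function(profile) {
  ok <- !profile$censored
  if (sum(ok) < 2L) stopf("AUC needs at least 2 quantifiable points")
  pracma::trapz(profile$time[ok], profile$concentration[ok])
}

#' Extrapolate AUC to infinity
#'
#' `AUC(0-inf) = AUC(0-t) + Clast / Ke`, with `Clast` the last measurable
#' concentration.
#'
#' @param auc_0_t AUC to the last quantifiable time, ug.h/mL.
#' @param c_last Last quantifiable concentration, ug/mL, >= 0.
#' @param ke Elimination rate constant, 1/h, > 0.
#' @return AUC(0-inf) in ug.h/mL (always >= `auc_0_t`).
#' @export
auc_to_infinity <- function(auc_0_t, c_last, ke) {
  check_scalar(ke, "ke", positive = TRUE)
  check_scalar(c_last, "c_last", nonnegative = TRUE)
  auc_0_t + c_last / ke
}

#' Full one-compartment analysis of a profile
#'
#' Orchestrates the estimation chain: terminal log-linear fit (Ke,
#' half-life), method of residuals (Ka), model tmax/Cmax from the fitted
#' rates and back-extrapolated intercept, observed Cmax/tmax read directly
#' from the data, trapezoidal AUC(0-t) and extrapolated AUC(0-inf). Errors
#' raised by a stage are reported with that stage's label.
#'
#' If the fitted rates come out with `ka < ke` the curve alone cannot say
#' which rate is absorption (flip-flop kinetics); the larger rate is
#' reported as Ka and `flip_flop` is flagged.
#'
#' @param profile A [conc_profile()].
#' @param rule Terminal-point selection rule, see [terminal_ke()].
#' @param allow_partial If `TRUE`, failure of the absorption-phase stages
#'   (method of residuals and the model tmax/Cmax that depend on Ka)
#'   yields `NA` for those fields plus a note, instead of an error. The
#'   terminal fit and the AUCs are always required.
#' @return A list of class `"pk_result"` with fields `ke`, `t_half`, `ka`,
#'   `tmax_model`, `cmax_model`, `cmax_observed`, `tmax_observed`,
#'   `auc_0_t`, `auc_0_inf`, `n_terminal_points`, `terminal_r_squared`,
#'   `flip_flop`, `notes`, and the profile labels.
#' @examples
#' p <- generate_profile(A = 10, ka = 1.5, ke = 0.15)
#' analyze_profile(p)
#' @export
analyze_profile <- function(profile, rule = "after_tmax", allow_partial = FALSE) {
  ok <- quantifiable(profile)
  if (!any(ok)) stopf("eligibility: profile is entirely below the LLOQ")
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", label, conditionMessage(e)))
  }
  tfit <- stage("terminal_ke", terminal_ke(profile, rule = rule))
  ke <- tfit$ke

  notes <- character(0)
  ka <- tryCatch(as.numeric(method_of_residuals(profile, tfit)),
                 error = function(e) e)
  if (inherits(ka, "error")) {
    if (!allow_partial)
      stopf("[method_of_residuals] %s", conditionMessage(ka))
    notes <- c(notes, paste("method_of_residuals:", conditionMessage(ka)))
    ka <- NA_real_
  }

  flip <- FALSE
  if (!is.na(ka) && ka < ke) {
    # flip-flop: the biexponential shape only identifies {min, max} rate
    flip <- TRUE
    tmp <- ke; ke <- ka; ka <- tmp
    notes <- c(notes, "flip_flop: fitted absorption rate below elimination rate; rates swapped so the larger is reported as Ka")
  }

  tmax_m <- if (!is.na(ka)) tmax_model(ka, ke) else NA_real_
  A_hat <- 10^tfit$intercept
  cmax_m <- if (!is.na(ka)) A_hat * (exp(-ke * tmax_m) - exp(-ka * tmax_m))
            else NA_real_

  tq <- profile$time[ok]
  cq <- profile$concentration[ok]
  i_max <- which.max(cq)

  auc_t <- stage("auc_trapezoid", auc_trapezoid(profile))
  c_last <- cq[length(cq)]
  auc_inf <- stage("auc_to_infinity", auc_to_infinity(auc_t, c_last, ke))

  structure(list(
    analyte_id = attr(profile, "analyte_id"),
    subject_id = attr(profile, "subject_id"),
    dose_mg = attr(profile, "dose_mg"),
    ke = ke, t_half = half_life(ke), ka = ka,
    tmax_model = tmax_m, cmax_model = cmax_m,
    cmax_observed = cq[i_max], tmax_observed = tq[i_max],
    auc_0_t = auc_t, auc_0_inf = auc_inf,
    n_terminal_points = tfit$n_points,
    terminal_r_squared = tfit$r_squared,
    flip_flop = flip, notes = notes
  ), class = "pk_result")
}

#' @export
print.pk_result <- function(x, ...) {
  cat(sprintf("PK result [%s / %s]\n", x$subject_id, x$analyte_id))
  cat(sprintf("  Ke %.4g 1/h   t1/2 %.4g h   Ka %.4g 1/h\n", x$ke, x$t_half, x$ka))
  cat(sprintf("  tmax (model/obs) %.4g / %.4g h   Cmax (model/obs) %.4g / %.4g ug/mL\n",
              x$tmax_model, x$tmax_observed, x$cmax_model, x$cmax_observed))
  cat(sprintf("  AUC0-t %.4g   AUC0-inf %.4g ug.h/mL  (terminal n=%d, r^2=%.4f)\n",
              x$auc_0_t, x$auc_0_inf, x$n_terminal_points, x$terminal_r_squared))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Tabulate PK results in conventional report order
#'
#' @param results A `pk_result` or list of them.
#' @param digits Display rounding (default 2 decimals); `NULL` disables.
#' @return A data frame with columns `subject_id`, `analyte_id`, `ke`,
#'   `t_half`, `tmax_observed`, `cmax_observed`, `auc_0_t`, `auc_0_inf`,
#'   plus `ka` and the model tmax/Cmax, in the column order bioanalytical
#'   reports use (Ke, t1/2, Tmax, Cmax, AUC0-t, AUC0-inf).
#' @export
pk_table <- function(results, digits = 2) {
  if (inherits(results, "pk_result")) results <- list(results)
  out <- do.call(rbind, lapply(results, function(x) {
    data.frame(subject_id = x$subject_id, analyte_id = x$analyte_id,
               ke = x$ke, t_half = x$t_half,
               tmax = x$tmax_observed, cmax = x$cmax_observed,
               auc_0_t = x$auc_0_t, auc_0_inf = x$auc_0_inf,
               ka = x$ka, tmax_model = x$tmax_model,
               cmax_model = x$cmax_model, flip_flop = x$flip_flop,
               notes = paste(x$notes, collapse = "; "))
  }))
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round, digits = digits)
  }
  rownames(out) <- NULL
  out
}
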