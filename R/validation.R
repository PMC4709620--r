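#' Accuracy as percent recovery
#'
#' @param nominal Nominal (spiked) concentration, ug/mL, > 0.
#' @param mean_found Mean measured concentration, ug/mL.
#' @return `100 * mean_found / nominal`, percent. Vectorised.
#' @export
recovery <- function(nominal, mean_found) {
  if (any(!is.finite(nominal)) || any(nominal <= 0))
    stopf("`nominal` must be > 0")
  100 * mean_found / nominal
}

#' Precision as relative standard deviation
#'
#' `rsd()` takes raw replicate values (sample SD, n-1 denominator);
#' `rsd_from_moments()` takes a mean/SD pair, e.g. when recomputing a
#' printed `mean +/- SD` summary.
#'
#' @param values Numeric replicate measurements, length >= 2, positive mean.
#' @return RSD in percent: `100 * sd / mean`.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stopf("RSD needs at least 2 replicates")
  rsd_from_moments(mean(values), sd(values))
}

#' @rdname rsd
#' @param mean_found,sd_found Mean and standard deviation of the replicates.
#' @export
rsd_from_moments <- function(mean_found, sd_found) {
  if (any(!is.finite(mean_found)) || any(mean_found <= 0))
    stopf("RSD is undefined for non-positive mean")
  if (any(sd_found < 0)) stopf("`sd_found` must be >= 0")
  100 * sd_found / mean_found
}

#' Construct a QC replicate set
#'
#' @param analyte_id Label.
#' @param nominal Nominal concentration, ug/mL, > 0.
#' @param measured Replicate measured concentrations (>= 2 for any SD-based
#'   summary).
#' @param period One of `"intraday"`, `"interday"`, `"short_term"`,
#'   `"long_term"`, or any study-specific condition label.
#' @return A list of class `"qc_set"`.
#' @export
qc_set <- function(analyte_id, nominal, measured, period = "intraday") {
  check_scalar(nominal, "nominal", positive = TRUE)
  if (length(measured) < 2L)
    stopf("a QC set needs at least 2 replicates")
  structure(list(analyte_id = as.character(analyte_id), nominal = nominal,
                 measured = as.numeric(measured),
                 period = as.character(period)),
            class = "qc_set")
}

validation_row <- function(analyte_id, period, nominal, measured, tol_pct = 15) {
  m <- mean(measured)
  s <- sd(measured)
  rec <- recovery(nominal, m)
  r <- rsd_from_moments(m, s)
  data.frame(analyte_id = analyte_id, period = period, nominal = nominal,
             mean_found = m, sd = s, recovery_pct = rec, rsd_pct = r,
             n = length(measured),
             pass = abs(rec - 100) <= tol_pct & r <= tol_pct)
}

#' Accuracy/precision assessment of one QC set
#'
#' Computes mean, sample SD, percent recovery and RSD for a replicate set
#' and applies the bioanalytical acceptance rule: recovery within +/-15% of
#' nominal and RSD at most 15%, both boundaries inclusive. Values are kept
#' at full precision; see [format_validation_table()] for display rounding.
#'
#' @param qc A [qc_set()].
#' @param tol_pct Acceptance half-width in percent (default 15).
#' @return A one-row `data.frame`: `analyte_id`, `period`, `nominal`,
#'   `mean_found`, `sd`, `recovery_pct`, `rsd_pct`, `n`, `pass`.
#' @examples
#' assess_qc(qc_set("CLP", 0.25, c(0.24, 0.24, 0.24)))
#' @export
assess_qc <- function(qc, tol_pct = 15) {
  if (!inherits(qc, "qc_set")) stopf("`qc` must be a qc_set")
  validation_row(qc$analyte_id, qc$period, qc$nominal, qc$measured, tol_pct)
}

#' Stability assessment of stored QC samples
#'
#' Identical arithmetic to [assess_qc()] with the +/-15% stability rule: a
#' condition passes when the mean stored concentration deviates from the
#' reference nominal by at most 15% (inclusive) with RSD at most 15%.
#'
#' @param reference_nominal Freshly-prepared reference concentration, ug/mL.
#' @param stored_measurements Replicate concentrations after storage.
#' @param condition Storage condition label (treated as an opaque string,
#'   e.g. `"short_term"`, `"long_term"`).
#' @param analyte_id Label.
#' @param tol_pct Acceptance half-width in percent (default 15).
#' @return A one-row `data.frame` as in [assess_qc()], with the condition
#'   in the `period` column.
#' @export
assess_stability <- function(reference_nominal, stored_measurements,
                             condition = "short_term", analyte_id = "analyte",
                             tol_pct = 15) {
  check_scalar(reference_nominal, "reference_nominal", positive = TRUE)
  if (length(stored_measurements) < 2L)
    stopf("stability assessment needs at least 2 replicates")
  validation_row(analyte_id, condition, reference_nominal,
                 stored_measurements, tol_pct)
}

#' Robustness summary of retention times across conditions
#'
#' For deliberately varied chromatographic conditions (flow rate, buffer
#' pH, ...) summarises per analyte and condition the mean retention time,
#' SD and RSD over replicate injections.
#'
#' @param runs A data frame with columns `condition`, `analyte_id`,
#'   `retention_time`, one row per injection. Every condition must cover
#'   the same analyte set, each with at least 2 replicates.
#' @return A `data.frame` with one row per condition x analyte:
#'   `condition`, `analyte_id`, `mean_rt`, `sd_rt`, `rsd_pct`, `n`.
#' @export
robustness_summary <- function(runs) {
  need <- c("condition", "analyte_id", "retention_time")
  if (!all(need %in% names(runs)))
    stopf("`runs` must have columns %s", paste(need, collapse = ", "))
  sets <- tapply(runs$analyte_id, runs$condition,
                 function(a) paste(sort(unique(a)), collapse = "|"))
  if (length(unique(sets)) != 1L)
    stopf("mismatched analyte sets across conditions")
  groups <- split(runs, list(runs$condition, runs$analyte_id), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    if (nrow(g) < 2L)
      stopf("condition '%s' has fewer than 2 replicates for '%s'",
            g$condition[1], g$analyte_id[1])
    data.frame(condition = g$condition[1], analyte_id = g$analyte_id[1],
               mean_rt = mean(g$retention_time), sd_rt = sd(g$retention_time),
               rsd_pct = if (mean(g$retention_time) > 0)
                 100 * sd(g$retention_time) / mean(g$retention_time)
               else NA_real_,
               n = nrow(g))
  }))
  out <- out[order(out$condition, out$analyte_id), ]
  rownames(out) <- NULL
  out
}

#' Percent recovery of a stressed sample
#'
#' Forced-degradation arithmetic: the parent-peak area of a stressed sample
#' as a percentage of the unstressed reference.
#'
#' @param reference_area Reference (unstressed) peak area, > 0.
#' @param stressed_area Peak area after stress, >= 0.
#' @return Recovery in percent.
#' @export
degradation_recovery <- function(reference_area, stressed_area) {
  if (any(!is.finite(reference_area)) || any(reference_area <= 0))
    stopf("`reference_area` must be > 0")
  100 * stressed_area / reference_area
}

#' Round half away from zero
#'
#' Commercial rounding as used in printed assay reports (96.5% recovery is
#' reported as 97, not banker's-rounded to 96).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Display rounding for validation tables
#'
#' Applies the conventional report rounding - concentrations and SD to 2
#' decimals, recovery to whole percent, RSD to 2 decimals, halves away
#' from zero - leaving the input untouched.
#'
#' @param rows Rows from [assess_qc()] / [assess_stability()] (rbind-able).
#' @return A data frame with rounded display columns.
#' @export
format_validation_table <- function(rows) {
  out <- rows
  out$mean_found <- round_half_up(out$mean_found, 2)
  out$sd <- round_half_up(out$sd, 2)
  out$recovery_pct <- round_half_up(out$recovery_pct)
  out$rsd_pct <- round_half_up(out$rsd_pct, 2)
  out
}
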