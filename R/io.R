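#' Read/write chromatograms and profiles as delimited text
#'
#' Chromatograms are stored as 2-column tab-separated text
#' (`time_min`, `signal`); concentration-time profiles as 3-column text
#' (`time_h`, `conc_ug_per_ml`, `censored`) with a YAML sidecar
#' (`<path>.meta.yaml`) holding the analyte, subject, dose and LLOQ.
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @return `write_*` return `path` invisibly; `read_*` return the
#'   reconstructed object.
#' @name chromapk_io
NULL

#' @rdname chromapk_io
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  df <- data.frame(time_min = chrom$time, signal = chrom$signal)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname chromapk_io
#' @export
read_chromatogram <- function(path) {
  df <- read.delim(path)
  chromatogram(df$time_min, df$signal)
}

#' @rdname chromapk_io
#' @param profile A [conc_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "conc_profile"))
  df <- data.frame(time_h = profile$time,
                   conc_ug_per_ml = profile$concentration,
                   censored = as.integer(profile$censored))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(analyte_id = attr(profile, "analyte_id"),
               subject_id = attr(profile, "subject_id"),
               dose_mg = attr(profile, "dose_mg"),
               lloq = attr(profile, "lloq"))
  tp <- attr(profile, "true_params")
  if (!is.null(tp)) meta$true_params <- tp
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname chromapk_io
#' @export
read_profile <- function(path) {
  df <- read.delim(path)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  dose <- meta$dose_mg
  conc_profile(df$time_h, df$conc_ug_per_ml,
               censored = as.logical(df$censored),
               lloq = if (is.null(meta$lloq)) 0 else meta$lloq,
               analyte_id = if (is.null(meta$analyte_id)) "analyte" else meta$analyte_id,
               subject_id = if (is.null(meta$subject_id)) "subject" else meta$subject_id,
               dose_mg = if (is.null(dose) || !is.numeric(dose)) NA_real_ else dose,
               true_params = meta$true_params)
}

#' Bundled reference summaries of the accompanying assay study
#'
#' Small plain-text tables transcribed from the published validation and
#' patient summaries of the clopidogrel / carboxylic-acid-metabolite /
#' atorvastatin HPLC-UV assay the package accompanies:
#'
#' * `"qc"` - intraday/interday QC summaries (nominal, mean found, SD, n)
#' * `"stability"` - short- and long-term stability summaries
#' * `"sst"` - reported system-suitability values and limits
#' * `"pk"` - per-patient pharmacokinetic parameters (Ke, t1/2, Tmax,
#'   Cmax, AUC0-t, AUC0-inf) with the printed decimal precision of t1/2
#'   recorded in `t_half_digits`
#'
#' These are the inputs the validation arithmetic is recomputed from; they
#' contain summary statistics only, no raw instrument data.
#'
#' @param which One of `"qc"`, `"stability"`, `"sst"`, `"pk"`.
#' @return A data frame.
#' @examples
#' head(reference_data("qc"))
#' @export
reference_data <- function(which = c("qc", "stability", "sst", "pk")) {
  which <- match.arg(which)
  file <- c(qc = "reference_qc_summary.tsv",
            stability = "reference_stability_summary.tsv",
            sst = "reference_sst.tsv",
            pk = "reference_pk_parameters.tsv")[[which]]
  path <- system.file("extdata", file, package = "chromaPK", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
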