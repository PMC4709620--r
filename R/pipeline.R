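#' Default pipeline configuration
#'
#' One nested list drives every stage: analyte metadata (retention windows,
#' peak shapes, calibration levels and generating curves, QC levels, LLOQ),
#' SST limits, the clinical sampling schedule, simulated-subject kinetics
#' and the master seed. The defaults encode the clopidogrel (CLP) /
#' carboxylic acid metabolite (CCA) / atorvastatin (ATV) assay with
#' ibuprofen internal standard (IS) that the package accompanies; see the
#' vignette for the provenance of each number.
#'
#' @return A nested list of class `"pipeline_config"`.
#' @seealso [run_pipeline()], [read_pipeline_config()]
#' @export
default_config <- function() {
  cfg <- list(
    seed = 101L,
    output_dir = "chromapk-output",
    chromatogram = list(duration = 20, sampling_rate = 5,
                        baseline_noise_sd = 0.2,
                        blank_region = c(16, 19)),
    sst_limits = list(rs_min = 2.0, t_max = 2.0, n_min = 2000),
    schedule = list(times = c(0, 0.25, 0.5, 1, 3, 6, 9, 12),
                    noise_cv = 0.05),
    qc = list(true_recovery = 0.96, cv = 0.04, n = 3,
              periods = c("intraday", "interday")),
    stability = list(true_recovery = 0.94, cv = 0.05, n = 3,
                     conditions = c("short_term", "long_term")),
    analytes = list(
      CCA = list(retention_time = 9.663, sigma = 0.080, tau = 0,
                 peak_area = 4, window = c(9.4, 9.9),
                 cal_levels = c(0.015, 0.03, 0.06, 0.125, 0.5, 4),
                 cal_slope = 0.2227, cal_intercept = 0.0158,
                 qc_levels = c(0.5, 1, 2, 4),
                 stability_levels = c(0.12, 4),
                 lloq = 0.01, height_response_slope = 900),
      ATV = list(retention_time = 10.998, sigma = 0.085, tau = 0.062,
                 peak_area = 3, window = c(10.7, 11.3),
                 cal_levels = c(0.005, 0.01, 0.02, 0.04, 0.08, 0.16,
                                0.32, 0.64, 1.28, 2.56),
                 cal_slope = 0.3404, cal_intercept = 0.0017,
                 qc_levels = c(0.2, 0.3, 1, 2.5),
                 stability_levels = c(0.5, 2.5),
                 lloq = 0.005, height_response_slope = 1800),
      IS = list(retention_time = 11.802, sigma = 0.090, tau = 0,
                peak_area = 6, window = c(11.5, 12.1)),
      CLP = list(retention_time = 12.682, sigma = 0.060, tau = 0.100,
                 peak_area = 5, window = c(12.4, 13.0),
                 cal_levels = c(0.008, 0.016, 0.032, 0.064, 0.128,
                                0.25, 0.5, 1, 2),
                 cal_slope = 0.3789, cal_intercept = 0.0004,
                 qc_levels = c(0.25, 0.5, 1, 2),
                 lloq = 0.008, height_response_slope = 1500)
    ),
    # simulated maintenance-therapy subjects; rates in 1/h, A in ug/mL
    subjects = list(
      patient1 = list(CLP = list(A = 0.13, ka = 12, ke = 0.81, dose_mg = 75),
                      CCA = list(A = 5.1, ka = 3.2, ke = 0.15, dose_mg = 75),
                      ATV = list(A = 0.13, ka = 0.85, ke = 0.08, dose_mg = 20)),
      patient2 = list(CLP = list(A = 0.10, ka = 12, ke = 0.58, dose_mg = 75),
                      CCA = list(A = 5.9, ka = 2.9, ke = 0.23, dose_mg = 75),
                      ATV = list(A = 0.21, ka = 0.90, ke = 0.08, dose_mg = 40)),
      patient3 = list(CLP = list(A = 0.09, ka = 12, ke = 1.02, dose_mg = 75),
                      CCA = list(A = 4.0, ka = 3.3, ke = 0.13, dose_mg = 75),
                      ATV = list(A = 0.26, ka = 0.80, ke = 0.07, dose_mg = 80))
    )
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML config and merges it over [default_config()], so a config
#' file only needs the fields it overrides.
#'
#' @param path Path to a YAML file, or `NULL` for the packaged defaults.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
    class(cfg) <- c("pipeline_config", "list")
  }
  validate_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` list to validate.
#' @export
validate_config <- function(config) {
  fail <- function(field, msg) stopf("invalid config field `%s`: %s", field, msg)
  if (is.null(config$seed) || !is.finite(config$seed)) fail("seed", "must be an integer")
  if (!is.character(config$output_dir)) fail("output_dir", "must be a path")
  lim <- config$sst_limits
  for (f in c("rs_min", "t_max", "n_min"))
    if (is.null(lim[[f]]) || lim[[f]] <= 0) fail(paste0("sst_limits$", f), "must be > 0")
  ts <- config$schedule$times
  if (is.null(ts) || any(diff(ts) <= 0) || any(ts < 0))
    fail("schedule$times", "must be non-negative and strictly increasing")
  if (config$schedule$noise_cv < 0) fail("schedule$noise_cv", "must be >= 0")
  ids <- names(config$analytes)
  if (anyDuplicated(ids)) fail("analytes", "analyte ids must be unique")
  for (id in ids) {
    a <- config$analytes[[id]]
    if (is.null(a$retention_time) || a$retention_time <= 0)
      fail(paste0("analytes$", id, "$retention_time"), "must be > 0")
    if (is.null(a$window) || length(a$window) != 2L || a$window[1] >= a$window[2])
      fail(paste0("analytes$", id, "$window"), "must be c(lower, upper)")
  }
  for (sid in names(config$subjects)) {
    for (aid in names(config$subjects[[sid]])) {
      if (!aid %in% ids)
        fail(paste0("subjects$", sid), sprintf("analyte '%s' is not defined", aid))
    }
  }
  invisible(config)
}

pipeline_path <- function(dir, ...) file.path(dir, paste0(...))

write_report <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the simulation / analysis pipeline
#'
#' Executes one or all stages against a configuration, writing every input
#' and report as delimited text under `output_dir` plus a JSON run manifest
#' (config hash, seed, package and R versions, files written). All
#' randomness derives from the master seed, so a rerun with the same config
#' and seed is byte-identical.
#'
#' Stages:
#' * `simulate` - chromatogram, calibration level tables, QC replicate
#'   table, stability table and per-subject concentration-time profiles;
#' * `sst` - peak detection on the simulated chromatogram and a
#'   system-suitability report against the configured limits;
#' * `calibrate` - calibration-curve fits plus S/N-based LOD/LLOQ per
#'   analyte;
#' * `validate` - accuracy/precision and stability assessment under the
#'   +/-15% rule;
#' * `pk` - one-compartment analysis of every profile (partial results
#'   with a note where a stage is infeasible, e.g. too few quantifiable
#'   absorption points);
#' * `all` - all of the above in order.
#'
#' @param config A `pipeline_config`, a path to a YAML config, or `NULL`
#'   for the defaults.
#' @param stage One of `"simulate"`, `"sst"`, `"calibrate"`, `"validate"`,
#'   `"pk"`, `"all"`. Analysis stages require the `simulate` outputs and
#'   will error if they are missing.
#' @param seed Optional master-seed override.
#' @param out_dir Optional output-directory override.
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with `status` (0 = all acceptance flags pass,
#'   2 = at least one SST or validation flag failed), `reports` (named file
#'   paths) and `manifest` (path to the JSON manifest).
#' @export
run_pipeline <- function(config = NULL, stage = "all", seed = NULL,
                         out_dir = NULL, quiet = FALSE) {
  stage <- match.arg(stage, c("simulate", "sst", "calibrate", "validate", "pk", "all"))
  if (is.null(config)) config <- default_config()
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(out_dir)) config$output_dir <- out_dir
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  log_msg <- function(...) if (!quiet) message(sprintf(...))
  stages <- if (stage == "all") c("simulate", "sst", "calibrate", "validate", "pk") else stage
  reports <- list()
  status <- 0L

  for (st in stages) {
    res <- switch(st,
      simulate = stage_simulate(config, log_msg),
      sst = stage_sst(config, log_msg),
      calibrate = stage_calibrate(config, log_msg),
      validate = stage_validate(config, log_msg),
      pk = stage_pk(config, log_msg))
    reports <- c(reports, res$reports)
    status <- max(status, res$status)
  }

  manifest <- list(
    seed = config$seed,
    config_hash = unname(config_hash(config)),
    package_version = as.character(packageVersion("chromaPK")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = stages,
    status = status,
    files = unname(unlist(reports))
  )
  manifest_path <- pipeline_path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = status, reports = reports, manifest = manifest_path))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  tools::md5sum(tmp)
}

# analytes that carry a calibration definition
quantified_analytes <- function(config) {
  ids <- names(config$analytes)
  ids[vapply(ids, function(id) !is.null(config$analytes[[id]]$cal_levels), TRUE)]
}

stage_simulate <- function(config, log_msg) {
  dir <- config$output_dir
  seed <- as.integer(config$seed)
  reports <- list()

  peaks <- lapply(names(config$analytes), function(id) {
    a <- config$analytes[[id]]
    peak_spec(id, a$retention_time, area = a$peak_area,
              sigma = a$sigma, tau = a$tau)
  })
  ch <- generate_chromatogram(peaks,
    duration = config$chromatogram$duration,
    sampling_rate = config$chromatogram$sampling_rate,
    baseline_noise_sd = config$chromatogram$baseline_noise_sd,
    seed = seed + 1L)
  reports$chromatogram <- write_chromatogram(ch, pipeline_path(dir, "chromatogram.tsv"))
  log_msg("simulate: chromatogram with %d peaks, %d samples",
          length(peaks), nrow(ch))

  # calibration level tables: exact reported line + replicate-level noise
  k <- 10L
  for (id in quantified_analytes(config)) {
    a <- config$analytes[[id]]
    is_area <- 10
    ratio <- a$cal_slope * a$cal_levels + a$cal_intercept
    sdlog <- sqrt(log1p(0.02^2))
    mult <- withr::with_seed(seed + k,
      rlnorm(length(ratio), -sdlog^2 / 2, sdlog))
    lv <- data.frame(analyte_id = id, concentration = a$cal_levels,
                     analyte_area = ratio * mult * is_area, is_area = is_area)
    reports[[paste0("cal_", id)]] <-
      write_report(lv, pipeline_path(dir, "calibration_levels_", id, ".tsv"))
    k <- k + 1L
  }

  # QC replicates (accuracy/precision periods + stability conditions)
  qc_rows <- list()
  for (id in quantified_analytes(config)) {
    a <- config$analytes[[id]]
    for (period in config$qc$periods) {
      for (nom in a$qc_levels) {
        vals <- generate_qc_replicates(nom, config$qc$true_recovery,
                                       config$qc$cv, config$qc$n,
                                       seed = seed + k)
        qc_rows[[length(qc_rows) + 1L]] <-
          data.frame(analyte_id = id, period = period, nominal = nom,
                     replicate = seq_along(vals), measured = vals)
        k <- k + 1L
      }
    }
    for (cond in config$stability$conditions) {
      for (nom in a$stability_levels %||% numeric(0)) {
        vals <- generate_qc_replicates(nom, config$stability$true_recovery,
                                       config$stability$cv, config$stability$n,
                                       seed = seed + k)
        qc_rows[[length(qc_rows) + 1L]] <-
          data.frame(analyte_id = id, period = cond, nominal = nom,
                     replicate = seq_along(vals), measured = vals)
        k <- k + 1L
      }
    }
  }
  qc <- do.call(rbind, qc_rows)
  reports$qc <- write_report(qc, pipeline_path(dir, "qc_replicates.tsv"))
  log_msg("simulate: %d QC replicate rows", nrow(qc))

  # subject profiles
  for (sid in names(config$subjects)) {
    for (aid in names(config$subjects[[sid]])) {
      p <- config$subjects[[sid]][[aid]]
      lloq <- config$analytes[[aid]]$lloq %||% 0
      prof <- generate_profile(p$A, p$ka, p$ke,
                               times = config$schedule$times,
                               lloq = lloq,
                               noise_cv = config$schedule$noise_cv,
                               seed = seed + k,
                               analyte_id = aid, subject_id = sid,
                               dose_mg = p$dose_mg %||% NA_real_)
      reports[[paste0("profile_", sid, "_", aid)]] <-
        write_profile(prof, pipeline_path(dir, "profile_", sid, "_", aid, ".tsv"))
      k <- k + 1L
    }
  }
  log_msg("simulate: %d subject profiles",
          sum(lengths(config$subjects)))
  list(reports = reports, status = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_sst <- function(config, log_msg) {
  dir <- config$output_dir
  ch_path <- pipeline_path(dir, "chromatogram.tsv")
  if (!file.exists(ch_path)) stopf("sst: run the simulate stage first (%s missing)", ch_path)
  ch <- read_chromatogram(ch_path)
  windows <- lapply(config$analytes, `[[`, "window")
  peaks <- detect_peaks(ch, min_height = 1, expected = windows)
  limits <- do.call(sst_limits, config$sst_limits)
  rep <- sst_evaluate(peaks, limits)
  path <- write_report(as.data.frame(rep), pipeline_path(dir, "sst_report.tsv"))
  log_msg("sst: %d analytes, %d pass", nrow(rep), sum(rep$pass))
  list(reports = list(sst = path),
       status = if (all(rep$pass)) 0L else 2L)
}

stage_calibrate <- function(config, log_msg) {
  dir <- config$output_dir
  rows <- list()
  ch_path <- pipeline_path(dir, "chromatogram.tsv")
  noise_pp <- NA_real_
  if (file.exists(ch_path)) {
    ch <- read_chromatogram(ch_path)
    br <- config$chromatogram$blank_region
    idx <- ch$time >= br[1] & ch$time <= br[2]
    fit <- lm(signal ~ time, data = ch[idx, ])
    noise_pp <- diff(range(resid(fit)))
  }
  for (id in quantified_analytes(config)) {
    path <- pipeline_path(dir, "calibration_levels_", id, ".tsv")
    if (!file.exists(path)) stopf("calibrate: %s missing; run simulate first", path)
    lv <- read.delim(path)
    curve <- fit_calibration(lv, analyte_id = id)
    a <- config$analytes[[id]]
    lim <- if (is.finite(noise_pp) && noise_pp > 0 &&
               !is.null(a$height_response_slope))
      estimate_limits(a$height_response_slope, noise_pp)
    else list(lod = NA_real_, lloq = NA_real_)
    rows[[id]] <- data.frame(analyte_id = id, slope = curve$slope,
                             intercept = curve$intercept,
                             r_squared = curve$r_squared,
                             range_low = curve$range_low,
                             range_high = curve$range_high,
                             n_levels = curve$n_levels,
                             lod = lim$lod, lloq = lim$lloq)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  path <- write_report(out, pipeline_path(dir, "calibration_report.tsv"))
  log_msg("calibrate: %d curves fitted (min r^2 %.5f)",
          nrow(out), min(out$r_squared))
  list(reports = list(calibration = path), status = 0L)
}

stage_validate <- function(config, log_msg) {
  dir <- config$output_dir
  qc_path <- pipeline_path(dir, "qc_replicates.tsv")
  if (!file.exists(qc_path)) stopf("validate: %s missing; run simulate first", qc_path)
  qc <- read.delim(qc_path)
  stability_conditions <- config$stability$conditions
  groups <- split(qc, list(qc$analyte_id, qc$period, qc$nominal), drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (g$period[1] %in% stability_conditions)
      assess_stability(g$nominal[1], g$measured, condition = g$period[1],
                       analyte_id = g$analyte_id[1])
    else
      assess_qc(qc_set(g$analyte_id[1], g$nominal[1], g$measured,
                       period = g$period[1]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$analyte_id, out$period, out$nominal), ]
  rownames(out) <- NULL
  path <- write_report(format_validation_table(out),
                       pipeline_path(dir, "validation_report.tsv"))
  log_msg("validate: %d QC sets, %d pass", nrow(out), sum(out$pass))
  list(reports = list(validation = path),
       status = if (all(out$pass)) 0L else 2L)
}

stage_pk <- function(config, log_msg) {
  dir <- config$output_dir
  results <- list()
  for (sid in names(config$subjects)) {
    for (aid in names(config$subjects[[sid]])) {
      path <- pipeline_path(dir, "profile_", sid, "_", aid, ".tsv")
      if (!file.exists(path)) stopf("pk: %s missing; run simulate first", path)
      prof <- read_profile(path)
      res <- tryCatch(analyze_profile(prof, allow_partial = TRUE),
                      error = function(e) e)
      if (inherits(res, "error")) {
        log_msg("pk: %s/%s skipped (%s)", sid, aid, conditionMessage(res))
        next
      }
      results[[length(results) + 1L]] <- res
    }
  }
  if (!length(results)) stopf("pk: no profile could be analysed")
  out <- pk_table(results, digits = NULL)
  path <- write_report(out, pipeline_path(dir, "pk_report.tsv"))
  log_msg("pk: %d profiles analysed, %d with notes",
          nrow(out), sum(nzchar(out$notes)))
  list(reports = list(pk = path), status = 0L)
}
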