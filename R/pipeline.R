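# Staged pipeline: simulate -> build-cohort -> classify -> patterns ->
# summarize, driven by one nested config, with CSV artifacts and a
# JSON-lines manifest (row counts, file hashes, config hash) per stage.

pipeline_stages <- function() {
  c("simulate", "build-cohort", "classify", "patterns", "summarize")
}

#' Default pipeline configuration
#'
#' Nested sections: `io` (date format), `cohort` (window lengths, see
#' [cohort_config()]), `classifier` (thresholds, see [classifier_config()]),
#' `simulation` (see [simulation_config()]; only scalar fields are exposed
#' in the file format), `output` (directory, log level).
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    io = list(date_format = "iso"),
    cohort = list(asthma_window_days = 91, baseline_days = 365, min_age = 4,
                  minor_exclusion_window_days = 91,
                  adult_exclusion_mode = "ever",
                  non_ocs_baseline_offset_days = 365),
    classifier = list(dose_high_mg = 20, dose_low_mg = 10,
                      event_window_days = 14, annual_nonintermittent_max = 2),
    simulation = list(n_patients = 500, seed = 1, prop_long_term = 0.05,
                      prop_non_ocs = 0.05, strict_gaps = TRUE),
    output = list(dir = "ocspatterns_out", log_level = "info"))
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop(sprintf("unknown config key: %s", full), call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML file with the sections of [default_run_config()]; unspecified keys
#' take their defaults, unknown keys are rejected with an error naming the
#' key.
#'
#' @param path Path to the YAML file (`NULL` for pure defaults).
#' @return Merged nested config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$output$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

hash_file <- function(path) unname(tools::md5sum(path))

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  hash_file(tmp)
}

manifest_append <- function(outdir, stage, files, counts, cfg_hash) {
  entry <- list(stage = stage, config_hash = cfg_hash,
                files = lapply(stats::setNames(files, basename(files)),
                               hash_file),
                row_counts = counts)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = file.path(outdir, "manifest.jsonl"), append = TRUE, sep = "")
}

read_stage_csv <- function(outdir, name, stage_needed) {
  p <- file.path(outdir, paste0(name, ".csv"))
  if (!file.exists(p)) {
    stop(sprintf("missing artifact %s.csv; run the '%s' stage first",
                 name, stage_needed), call. = FALSE)
  }
  data.table::fread(p)
}

as_date_cols <- function(dt, cols) {
  for (cl in intersect(cols, names(dt))) {
    data.table::set(dt, j = cl, value = as.Date(dt[[cl]]))
  }
  dt
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, reading any upstream artifacts
#' from `outdir` when their stage is not part of this run. Each stage
#' writes its CSVs and a manifest line; a rerun on identical inputs writes
#' identical artifact hashes. Row counts are conserved and asserted across
#' stage boundaries (patients in = eligible + attrition; OCS scripts in =
#' labelled scripts out).
#'
#' @param config Nested config from [read_run_config()] /
#'   [default_run_config()].
#' @param stages Character subset of
#'   `simulate, build-cohort, classify, patterns, summarize` (any contiguous
#'   run; defaults to all).
#' @param outdir Output directory (overrides `config$output$dir`).
#' @param seed Optional integer overriding `config$simulation$seed`.
#' @return Invisibly, a list with the stage artifacts produced.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = pipeline_stages(), outdir = NULL,
                         seed = NULL) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  if (!is.null(seed)) config$simulation$seed <- as.integer(seed)
  if (is.null(outdir)) outdir <- config$output$dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(config)
  yaml::write_yaml(config, file.path(outdir, "config_echo.yaml"))
  out <- list()

  ccfg <- do.call(cohort_config, config$cohort)
  kcfg <- do.call(classifier_config, config$classifier)

  if ("simulate" %in% stages) {
    sim <- simulate_cohort(do.call(simulation_config, config$simulation))
    files <- write_ehr_tables(sim, outdir)
    manifest_append(outdir, "simulate", files,
                    lapply(sim, nrow), cfg_hash)
    pipeline_log(config, "simulate: %d patients, %d prescriptions, %d events",
                 nrow(sim$patients), nrow(sim$prescriptions), nrow(sim$events))
    out$simulate <- sim
  }

  load_inputs <- function() {
    tabs <- list(
      patients = read_stage_csv(outdir, "patients", "simulate"),
      prescriptions = read_stage_csv(outdir, "prescriptions", "simulate"),
      events = read_stage_csv(outdir, "events", "simulate"))
    as_date_cols(tabs$patients,
                 c("birth_date", "registration_start", "registration_end"))
    as_date_cols(tabs$prescriptions, "date")
    as_date_cols(tabs$events, "date")
    tabs$prescriptions[is.na(instruction_text), instruction_text := ""]
    tabs
  }

  if ("build-cohort" %in% stages) {
    tabs <- load_inputs()
    res <- build_cohort(tabs$patients, tabs$prescriptions, tabs$events, ccfg)
    stopifnot(nrow(res$cohort) == nrow(tabs$patients))
    files <- write_ehr_tables(res, outdir)
    manifest_append(outdir, "build-cohort", files,
                    list(patients_in = nrow(tabs$patients),
                         eligible = sum(res$cohort$eligible),
                         removed = sum(res$attrition$n_removed)), cfg_hash)
    pipeline_log(config, "build-cohort: %d/%d eligible",
                 sum(res$cohort$eligible), nrow(res$cohort))
    out$cohort <- res
  }

  if ("classify" %in% stages) {
    tabs <- load_inputs()
    cohort <- as_date_cols(read_stage_csv(outdir, "cohort", "build-cohort"),
                           "index_date")
    cls <- classify_cohort(cohort, tabs$prescriptions, tabs$events, kcfg)
    n_ocs_in <- sum(tabs$prescriptions$therapy_class == "OCS" &
                      tabs$prescriptions$patient_id %in%
                        cohort$patient_id[cohort$eligible & cohort$arm == "ocs"])
    stopifnot(nrow(cls$scripts) == n_ocs_in)
    files <- c(file.path(outdir, "classified_scripts.csv"),
               file.path(outdir, "classified_patients.csv"))
    data.table::fwrite(cls$scripts, files[1])
    data.table::fwrite(cls$patients, files[2])
    manifest_append(outdir, "classify", files,
                    list(scripts_in = n_ocs_in,
                         scripts_out = nrow(cls$scripts),
                         patients = nrow(cls$patients)), cfg_hash)
    pipeline_log(config, "classify: %d scripts labelled (thresholds: high=%g low=%g mg/day, window=%d d, annual max=%d)",
                 nrow(cls$scripts), kcfg$dose_high_mg, kcfg$dose_low_mg,
                 kcfg$event_window_days, kcfg$annual_nonintermittent_max)
    out$classified <- cls
  }

  if ("patterns" %in% stages) {
    cls <- list(
      scripts = as_date_cols(
        read_stage_csv(outdir, "classified_scripts", "classify"), "date"),
      patients = read_stage_csv(outdir, "classified_patients", "classify"))
    prof <- pattern_profiles(cls)
    stopifnot(nrow(prof) ==
                sum(cls$patients$patient_use == "intermittent_only"))
    f <- file.path(outdir, "profiles.csv")
    data.table::fwrite(prof, f)
    manifest_append(outdir, "patterns", f,
                    list(intermittent_only = nrow(prof)), cfg_hash)
    pipeline_log(config, "patterns: %d intermittent-only patients profiled",
                 nrow(prof))
    out$profiles <- prof
  }

  if ("summarize" %in% stages) {
    prof <- read_stage_csv(outdir, "profiles", "patterns")
    tabs <- load_inputs()
    cohort <- as_date_cols(read_stage_csv(outdir, "cohort", "build-cohort"),
                           "index_date")
    cls_scripts <- read_stage_csv(outdir, "classified_scripts", "classify")
    summary_tab <- summarize_patterns(prof)
    strata <- stratify_cohort(cohort[cohort$patient_id %in% prof$patient_id],
                              tabs$prescriptions)
    strat <- stratified_summary(prof, strata)
    chisq_report <- data.table::data.table(
      comparison = c("saba_band", "age_band"),
      statistic = c(strat$by_saba$statistic, strat$by_age$statistic),
      df = c(strat$by_saba$df, strat$by_age$df),
      p_value = c(strat$by_saba$p_value, strat$by_age$p_value))
    files <- file.path(outdir, c("pattern_summary.csv", "table_saba.csv",
                                 "table_age.csv", "chisq.csv",
                                 "gina_distribution.csv",
                                 "dose_histogram.csv"))
    data.table::fwrite(summary_tab, files[1])
    data.table::fwrite(data.table::as.data.table(strat$by_saba$counts,
                                                 keep.rownames = "saba_band"),
                       files[2])
    data.table::fwrite(data.table::as.data.table(strat$by_age$counts,
                                                 keep.rownames = "age_band"),
                       files[3])
    data.table::fwrite(chisq_report, files[4])
    data.table::fwrite(strat$gina_distribution, files[5])
    data.table::fwrite(dose_histogram(cls_scripts), files[6])
    manifest_append(outdir, "summarize", files,
                    list(profiles = nrow(prof),
                         summary_rows = nrow(summary_tab)), cfg_hash)
    pipeline_log(config, "summarize: %d summary rows; chi-square saba %.3f (df %d), age %.3f (df %d)",
                 nrow(summary_tab), chisq_report$statistic[1],
                 chisq_report$df[1], chisq_report$statistic[2],
                 chisq_report$df[2])
    out$summary <- list(patterns = summary_tab, stratified = strat)
  }
  invisible(out)
}
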