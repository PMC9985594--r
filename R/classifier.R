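# Stepwise prescription classifier: instruction -> daily dose ->
# concurrent LRTI/exacerbation -> annual non-intermittent count. The first
# decisive step wins; the chain is biased toward specificity for
# intermittent use (any hint of maintenance prescribing yields long_term).

#' Default instruction rulebook
#'
#' The ordered pattern table used by [parse_instruction()]: each row has a
#' `priority` (lower matches first), a regular-expression `pattern` matched
#' case-insensitively, and a `verdict` (`intermittent` or `long_term`).
#' Maintenance phrases ("long term", "continuous", "repeat dispensing", ...)
#' rank before course/taper phrases ("then stop", "for N days", "reducing",
#' "short course", ...) so that mixed wording resolves conservatively.
#'
#' @param path Optional path to an alternative rulebook CSV.
#' @return data.table with columns `priority`, `pattern`, `verdict`,
#'   sorted by priority.
#' @export
default_rulebook <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "instruction_rules.csv",
                        package = "ocspatterns")
  }
  rb <- data.table::fread(path)
  stopifnot(all(c("priority", "pattern", "verdict") %in% names(rb)),
            all(rb$verdict %in% c("intermittent", "long_term")))
  data.table::setorder(rb, priority)
  rb[]
}

#' Classifier configuration
#'
#' @param dose_high_mg Prednisolone-equivalent mg/day at or above which a
#'   script is treated as an acute (intermittent) course; default 20.
#' @param dose_low_mg mg/day at or below which a script is treated as
#'   maintenance (long-term); default 10. Doses strictly between the two
#'   thresholds are undecided at the dose step.
#' @param event_window_days Half-width (days) of the symmetric window around
#'   a script date within which an LRTI or exacerbation event marks the
#'   script intermittent; default 14.
#' @param annual_nonintermittent_max Maximum number of otherwise-undecided
#'   scripts within a trailing 365-day window that are still labelled
#'   intermittent; default 2 (repeated acute courses, >= 2/year).
#' @param rulebook Instruction rulebook; default [default_rulebook()].
#' @param ddd DDD lookup table; default [ddd_table()].
#' @return Named list of settings.
#' @export
classifier_config <- function(dose_high_mg = 20, dose_low_mg = 10,
                              event_window_days = 14,
                              annual_nonintermittent_max = 2,
                              rulebook = default_rulebook(),
                              ddd = ddd_table()) {
  stopifnot(dose_low_mg < dose_high_mg, event_window_days > 0,
            annual_nonintermittent_max >= 0)
  list(dose_high_mg = dose_high_mg, dose_low_mg = dose_low_mg,
       event_window_days = as.integer(event_window_days),
       annual_nonintermittent_max = as.integer(annual_nonintermittent_max),
       rulebook = rulebook, ddd = ddd)
}

#' Classify a dosing instruction against the rulebook
#'
#' Returns the verdict of the first (lowest-priority-value) matching rule;
#' `"undecided"` when no rule matches or the text is empty. Free text never
#' raises an error.
#'
#' @param instruction_text Character vector.
#' @param rulebook As from [default_rulebook()].
#' @return Character vector in `{"intermittent", "long_term", "undecided"}`.
#' @export
parse_instruction <- function(instruction_text, rulebook = default_rulebook()) {
  out <- rep("undecided", length(instruction_text))
  text <- ifelse(is.na(instruction_text), "", instruction_text)
  open <- nzchar(trimws(text))
  for (i in seq_len(nrow(rulebook))) {
    if (!any(open)) break
    hit <- open & grepl(rulebook$pattern[i], text, ignore.case = TRUE)
    out[hit] <- rulebook$verdict[i]
    open <- open & !hit
  }
  out
}

#' Classify a script by prednisolone-equivalent daily dose
#'
#' @param pred_equiv_mg_per_day Numeric vector of prednisolone-equivalent
#'   mg/day (must be non-negative; `NA` allowed and returned undecided).
#' @param config [classifier_config()].
#' @return `"intermittent"` for doses `>= dose_high_mg`, `"long_term"` for
#'   doses `<= dose_low_mg`, `"undecided"` strictly between or unknown.
#' @export
classify_by_dose <- function(pred_equiv_mg_per_day,
                             config = classifier_config()) {
  if (any(pred_equiv_mg_per_day < 0, na.rm = TRUE)) {
    stop("negative prednisolone-equivalent dose; invalid record", call. = FALSE)
  }
  out <- rep("undecided", length(pred_equiv_mg_per_day))
  out[!is.na(pred_equiv_mg_per_day) &
        pred_equiv_mg_per_day >= config$dose_high_mg] <- "intermittent"
  out[!is.na(pred_equiv_mg_per_day) &
        pred_equiv_mg_per_day <= config$dose_low_mg] <- "long_term"
  out
}

#' Classify a script by concurrent LRTI or exacerbation
#'
#' A script is intermittent when an LRTI or asthma exacerbation event lies
#' within +/- `window` days of the prescription date; otherwise undecided.
#'
#' @param rx_date Vector of prescription dates.
#' @param events This patient's clinical events (data.table).
#' @param window Half-width in days; default from [classifier_config()].
#' @return Character vector in `{"intermittent", "undecided"}`.
#' @export
classify_by_concurrent_event <- function(rx_date, events, window = 14) {
  ed <- events$date[events$category %in% c("lrti", "exacerbation")]
  if (!length(ed)) return(rep("undecided", length(rx_date)))
  vapply(as.list(rx_date), function(d) {
    if (any(abs(as.integer(ed - d)) <= window)) "intermittent" else "undecided"
  }, character(1))
}

#' Classify residual scripts by annual non-intermittent count
#'
#' For each still-undecided script (sorted by date), count the undecided
#' scripts within the trailing 365-day window ending at (and including) the
#' script. A count of at most `annual_max` labels the script intermittent
#' (an isolated acute course); a larger count labels it long-term, since
#' several unexplained scripts inside one year imply maintenance use.
#'
#' @param dates Sorted dates of the undecided scripts of one patient.
#' @param annual_max Maximum count still considered intermittent.
#' @return Character vector in `{"intermittent", "long_term"}`, one per date.
#' @export
classify_by_annual_count <- function(dates, annual_max = 2) {
  if (!length(dates)) return(character(0))
  if (is.unsorted(dates)) stop("dates must be sorted", call. = FALSE)
  vapply(seq_along(dates), function(i) {
    n_in_window <- sum(dates >= dates[i] - 364L & dates <= dates[i])
    if (n_in_window <= annual_max) "intermittent" else "long_term"
  }, character(1))
}

#' Classify all OCS prescriptions of one patient
#'
#' Runs each OCS script through the stepwise chain instruction -> dose ->
#' concurrent event -> annual count; the first decisive step fixes the label
#' and is recorded as `decision_step`. Scripts with unknown substance or
#' unparseable dose skip the dose step. The patient-level summary is
#' `intermittent_only` when every script is intermittent, `any_long_term`
#' otherwise.
#'
#' @param scripts data.table of one patient's prescriptions (OCS rows are
#'   classified; other therapy classes are ignored).
#' @param events data.table of the same patient's clinical events.
#' @param config [classifier_config()].
#' @return List with `scripts` (columns `patient_id`, `date`, `drug`,
#'   `pred_equiv_mg_per_day`, `label`, `decision_step`) and `patient_use`.
#' @export
classify_patient <- function(scripts, events, config = classifier_config()) {
  ocs <- scripts[scripts$therapy_class == "OCS"]
  if (!nrow(ocs)) {
    stop("patient has no OCS prescriptions; nothing to classify", call. = FALSE)
  }
  ocs <- ocs[order(ocs$date)]
  n <- nrow(ocs)
  label <- rep(NA_character_, n)
  step <- rep(NA_character_, n)

  # step 1: dosing instruction
  v <- parse_instruction(ocs$instruction_text, config$rulebook)
  decided <- v != "undecided"
  label[decided] <- v[decided]
  step[decided] <- "instruction"

  # step 2: prednisolone-equivalent daily dose (unknown substance or
  # unparseable dose falls through)
  daily <- daily_dose_from_script(ocs$strength_mg_per_unit,
                                  ocs$quantity_units, ocs$instruction_text)
  known_drug <- tolower(ocs$drug) %in% tolower(config$ddd$substance)
  pred <- rep(NA_real_, n)
  pred[known_drug] <- to_prednisolone_equivalent(ocs$drug[known_drug],
                                                 daily[known_drug], config$ddd)
  open <- is.na(label)
  v <- classify_by_dose(pred, config)
  hit <- open & v != "undecided"
  label[hit] <- v[hit]
  step[hit] <- "dose"

  # step 3: concurrent LRTI/exacerbation
  open <- is.na(label)
  if (any(open)) {
    v <- classify_by_concurrent_event(ocs$date[open], events,
                                      config$event_window_days)
    hit <- which(open)[v != "undecided"]
    label[hit] <- "intermittent"
    step[hit] <- "concurrent_event"
  }

  # step 4: annual count of residual non-intermittent scripts
  open <- is.na(label)
  if (any(open)) {
    v <- classify_by_annual_count(ocs$date[open],
                                  config$annual_nonintermittent_max)
    label[open] <- v
    step[open] <- "annual_count"
  }

  out <- data.table::data.table(
    patient_id = ocs$patient_id, date = ocs$date, drug = ocs$drug,
    pred_equiv_mg_per_day = pred, label = label, decision_step = step)
  use <- if (all(label == "intermittent")) "intermittent_only" else "any_long_term"
  list(scripts = out, patient_use = use)
}

#' Classify every eligible OCS-arm patient in a cohort
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param prescriptions,events Normalized tables.
#' @param config [classifier_config()].
#' @return List with `scripts` (all classified OCS scripts) and `patients`
#'   (`patient_id`, `patient_use`).
#' @export
classify_cohort <- function(cohort, prescriptions, events,
                            config = classifier_config()) {
  ids <- cohort$patient_id[cohort$eligible & cohort$arm == "ocs"]
  rx_split <- split(prescriptions[prescriptions$patient_id %in% ids],
                    by = "patient_id")
  ev_split <- split(events[events$patient_id %in% ids], by = "patient_id")
  empty_ev <- events[0]
  res <- lapply(ids, function(id) {
    ev <- ev_split[[id]]
    if (is.null(ev)) ev <- empty_ev
    classify_patient(rx_split[[id]], ev, config)
  })
  list(
    scripts = data.table::rbindlist(lapply(res, `[[`, "scripts")),
    patients = data.table::data.table(
      patient_id = ids,
      patient_use = vapply(res, `[[`, character(1), "patient_use")))
}
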