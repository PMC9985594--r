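# Cohort construction: index date at first OCS prescription, inclusion and
# exclusion rules applied in a fixed, logged order, full attrition accounting.

#' Cohort-building configuration
#'
#' @param asthma_window_days Concurrency window (days) around the index date
#'   within which an asthma event must occur; default 91 days ("within 3
#'   months" with months of 30.33 days).
#' @param baseline_days Minimum registered baseline before the index date;
#'   default 365 days.
#' @param min_age Minimum age (completed years) at index; default 4.
#' @param minor_exclusion_window_days For patients aged 4 to <18, a chronic
#'   exclusion condition only excludes when diagnosed within this many days
#'   of an OCS prescription; default 91.
#' @param adult_exclusion_mode `"ever"` (default): adults with a listed
#'   chronic condition anywhere in their record are excluded. `"concurrent"`:
#'   adults are treated like minors (condition must be concurrent with OCS).
#' @param non_ocs_baseline_offset_days Reference date for the non-OCS arm is
#'   `registration_start + non_ocs_baseline_offset_days`; default 365.
#' @return Named list of settings.
#' @export
cohort_config <- function(asthma_window_days = 91, baseline_days = 365,
                          min_age = 4, minor_exclusion_window_days = 91,
                          adult_exclusion_mode = c("ever", "concurrent"),
                          non_ocs_baseline_offset_days = 365) {
  stopifnot(asthma_window_days > 0, baseline_days > 0,
            minor_exclusion_window_days > 0)
  list(asthma_window_days = as.integer(asthma_window_days),
       baseline_days = as.integer(baseline_days),
       min_age = as.integer(min_age),
       minor_exclusion_window_days = as.integer(minor_exclusion_window_days),
       adult_exclusion_mode = match.arg(adult_exclusion_mode),
       non_ocs_baseline_offset_days = as.integer(non_ocs_baseline_offset_days))
}

#' Index date: first OCS prescription
#'
#' @param prescriptions data.table of one patient's prescriptions.
#' @return The earliest `date` with `therapy_class == "OCS"`, or `NA` if the
#'   patient never received an OCS prescription.
#' @export
find_index_date <- function(prescriptions) {
  d <- prescriptions$date[prescriptions$therapy_class == "OCS"]
  if (!length(d)) return(as.Date(NA))
  min(d)
}

# Dates that count as an asthma event: coded diagnosis/consultation events
# plus asthma-therapy prescriptions.
asthma_event_dates <- function(events, prescriptions) {
  c(events$date[events$category %in% c("asthma_diagnosis", "asthma_consultation")],
    prescriptions$date[prescriptions$therapy_class %in% asthma_therapy_classes()])
}

#' Inclusion check for one patient
#'
#' Rules in fixed order: minimum age at index, an asthma event (coded event
#' or asthma-therapy prescription) within the concurrency window of the
#' index date, and at least `baseline_days` of registration before index.
#' The reason reported is the first failing rule.
#'
#' @param patient One-row data.table from the patients table.
#' @param index_date Index date (first OCS prescription, or the non-OCS-arm
#'   reference date).
#' @param events,prescriptions This patient's rows.
#' @param config [cohort_config()].
#' @return List with `eligible` (logical) and `reason` (one of `"none"`,
#'   `"age_below_minimum"`, `"no_concurrent_asthma_event"`,
#'   `"insufficient_baseline"`).
#' @export
check_inclusion <- function(patient, index_date, events, prescriptions,
                            config = cohort_config()) {
  age <- age_at(patient$birth_date, index_date)
  if (age < config$min_age) {
    return(list(eligible = FALSE, reason = "age_below_minimum"))
  }
  ad <- asthma_event_dates(events, prescriptions)
  if (!length(ad) ||
      !any(abs(as.integer(ad - index_date)) <= config$asthma_window_days)) {
    return(list(eligible = FALSE, reason = "no_concurrent_asthma_event"))
  }
  if (patient$registration_start > index_date - config$baseline_days) {
    return(list(eligible = FALSE, reason = "insufficient_baseline"))
  }
  list(eligible = TRUE, reason = "none")
}

#' Chronic-condition exclusion check for one patient
#'
#' Adults (>= 18 at index) are excluded if a listed chronic condition (see
#' [exclusion_conditions()]) appears anywhere in their record (default mode);
#' minors are excluded only when a condition diagnosis is concurrent with an
#' OCS prescription (within `minor_exclusion_window_days`).
#'
#' @param events This patient's clinical events.
#' @param age_at_index Completed years at index.
#' @param ocs_dates Dates of this patient's OCS prescriptions.
#' @param config [cohort_config()].
#' @return List with `excluded` (logical) and `condition` (name or `"none"`).
#' @export
check_exclusion_conditions <- function(events, age_at_index, ocs_dates,
                                       config = cohort_config()) {
  is_cond <- startsWith(events$category, "exclusion_condition:")
  if (!any(is_cond)) return(list(excluded = FALSE, condition = "none"))
  cond_events <- events[is_cond]
  concurrent_required <- age_at_index < 18 ||
    config$adult_exclusion_mode == "concurrent"
  if (!concurrent_required) {
    return(list(excluded = TRUE,
                condition = sub("^exclusion_condition:", "",
                                cond_events$category[1])))
  }
  if (length(ocs_dates)) {
    for (i in seq_len(nrow(cond_events))) {
      if (any(abs(as.integer(ocs_dates - cond_events$date[i])) <=
              config$minor_exclusion_window_days)) {
        return(list(excluded = TRUE,
                    condition = sub("^exclusion_condition:", "",
                                    cond_events$category[i])))
      }
    }
  }
  list(excluded = FALSE, condition = "none")
}

#' Build the study cohort with an attrition log
#'
#' Assigns each patient an arm (`ocs` if they have any OCS prescription,
#' `non_ocs` otherwise), sets the index date (first OCS prescription, or
#' `registration_start + non_ocs_baseline_offset_days` for the non-OCS arm),
#' and applies the inclusion and exclusion rules in a fixed order:
#' age, concurrent asthma event, baseline length, chronic exclusion
#' conditions. The attrition log reports the number removed by each rule in
#' application order; counts conserve (eligible + excluded = input patients).
#'
#' @param patients,prescriptions,events Normalized tables from
#'   [read_ehr_tables()] or [simulate_cohort()].
#' @param config [cohort_config()].
#' @return List with `cohort` (one row per input patient: `patient_id`,
#'   `arm`, `index_date`, `age_at_index`, `eligible`, `exclusion_reason`)
#'   and `attrition` (`rule`, `n_removed`, in application order).
#' @export
build_cohort <- function(patients, prescriptions, events,
                         config = cohort_config()) {
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  rx_split <- split(prescriptions, by = "patient_id")
  ev_split <- split(events, by = "patient_id")
  empty_rx <- prescriptions[0]
  empty_ev <- events[0]

  n <- nrow(patients)
  out <- data.table::data.table(
    patient_id = patients$patient_id,
    arm = character(n), index_date = as.Date(rep(NA, n)),
    age_at_index = integer(n), eligible = logical(n),
    exclusion_reason = character(n))
  rules <- c("age_below_minimum", "no_concurrent_asthma_event",
             "insufficient_baseline", "exclusion_condition")
  removed <- stats::setNames(integer(length(rules)), rules)

  for (i in seq_len(n)) {
    p <- patients[i]
    rx <- rx_split[[p$patient_id]]
    if (is.null(rx)) rx <- empty_rx
    ev <- ev_split[[p$patient_id]]
    if (is.null(ev)) ev <- empty_ev
    idx <- find_index_date(rx)
    if (is.na(idx)) {
      arm <- "non_ocs"
      idx <- p$registration_start + config$non_ocs_baseline_offset_days
    } else {
      arm <- "ocs"
    }
    age <- age_at(p$birth_date, idx)
    inc <- check_inclusion(p, idx, ev, rx, config)
    if (!inc$eligible) {
      reason <- inc$reason
      removed[reason] <- removed[reason] + 1L
    } else {
      ocs_dates <- rx$date[rx$therapy_class == "OCS"]
      exc <- check_exclusion_conditions(ev, age, ocs_dates, config)
      if (exc$excluded) {
        reason <- "exclusion_condition"
        removed[reason] <- removed[reason] + 1L
      } else {
        reason <- "none"
      }
    }
    data.table::set(out, i, j = c("arm", "index_date", "age_at_index",
                                  "eligible", "exclusion_reason"),
                    value = list(arm, idx, age, reason == "none", reason))
  }
  attrition <- data.table::data.table(rule = rules,
                                      n_removed = as.integer(removed))
  stopifnot(sum(out$eligible) + sum(attrition$n_removed) == n)
  list(cohort = out[], attrition = attrition)
}
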