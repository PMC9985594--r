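# Synthetic cohort generator: the three EHR-style tables with per-patient
# and per-script ground truth, so the full pipeline can be validated
# end-to-end without access-restricted primary-care data.

# Strict-mode gap sampling ranges sit strictly inside the category bounds
# (and >= 30 days for the frequent category, so planted concurrent events
# stay unambiguous relative to neighbouring scripts).
gap_sampling_ranges <- function(strict = TRUE) {
  if (strict) {
    list(frequent = 30:88, moderately_frequent = 91:180,
         infrequent = 183:363, sporadic = 366:500)
  } else {
    list(frequent = 1:89, moderately_frequent = 90:181,
         infrequent = 182:364, sporadic = 365:600)
  }
}

# Invert detailed_label(): label -> category subset.
label_category_map <- function() {
  lv <- gap_category_levels()
  subsets <- c(list(character(0)),
               lapply(seq_len(15), function(m) lv[bitwAnd(m, 2^(0:3)) > 0]))
  stats::setNames(subsets, vapply(subsets, detailed_label, character(1)))
}

#' Simulation configuration
#'
#' Defaults emulate the published UK cohort's conditions: the pattern
#' mixture follows the published detailed breakdown
#' ([reference_pattern_counts()]), the GINA-step, SABA-band and age-band
#' mixtures follow the published stratifier distributions, and gap sampling
#' in strict mode stays strictly inside the category boundaries so
#' ground-truth recovery is unambiguous.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; fully determines the output.
#' @param pattern_mixture Named probabilities over the 16 detailed pattern
#'   labels (normalised internally).
#' @param step_mixture Probabilities over the classifier decision step
#'   planted per intermittent script (`instruction`, `dose`,
#'   `concurrent_event`, `annual_count`). At most 2 `annual_count` scripts
#'   are planted per patient so their ground-truth label stays intermittent
#'   by construction.
#' @param prop_long_term Fraction of otherwise-eligible OCS-arm patients
#'   given one maintenance (long-term) script.
#' @param prop_non_ocs Fraction of patients with no OCS prescription ever
#'   (non-OCS arm).
#' @param ineligible Named fractions of planted rule violations:
#'   `age`, `no_asthma`, `baseline`, `excl_adult`, `excl_minor`.
#' @param gina_mixture,saba_mixture,age_mixture Stratifier target mixtures.
#' @param strict_gaps Strict-mode gap sampling (see above); when `FALSE`,
#'   gaps may land exactly on category boundaries to exercise tie handling.
#' @param index_start,index_end Range from which index dates are drawn.
#' @return Named list of settings.
#' @export
simulation_config <- function(
    n_patients = 500, seed = 1L,
    pattern_mixture = NULL,
    step_mixture = c(instruction = 0.5, dose = 0.3,
                     concurrent_event = 0.15, annual_count = 0.05),
    prop_long_term = 0.05, prop_non_ocs = 0.05,
    ineligible = c(age = 0.02, no_asthma = 0.02, baseline = 0.02,
                   excl_adult = 0.02, excl_minor = 0.01),
    gina_mixture = c(none = 0.138, `1` = 0.251, `2` = 0.320, `3` = 0.184,
                     `4` = 0.087, `5` = 0.020),
    saba_mixture = c(`0` = 0.238, `1-2` = 0.449, `>=3` = 0.314),
    age_mixture = c(child = 0.162, adolescent = 0.076, adult = 0.762),
    strict_gaps = TRUE,
    index_start = "2010-01-01", index_end = "2014-12-31") {
  if (is.null(pattern_mixture)) {
    ref <- reference_pattern_counts()
    pattern_mixture <- stats::setNames(ref$n / sum(ref$n), ref$label)
  }
  stopifnot(setequal(names(pattern_mixture), all_detailed_labels()),
            abs(sum(pattern_mixture) - 1) < 1e-6,
            abs(sum(step_mixture) - 1) < 1e-6,
            all(ineligible >= 0), sum(ineligible) + prop_non_ocs < 1,
            n_patients >= 1)
  list(n_patients = as.integer(n_patients), seed = as.integer(seed),
       pattern_mixture = pattern_mixture, step_mixture = step_mixture,
       prop_long_term = prop_long_term, prop_non_ocs = prop_non_ocs,
       ineligible = ineligible, gina_mixture = gina_mixture,
       saba_mixture = saba_mixture, age_mixture = age_mixture,
       strict_gaps = strict_gaps,
       index_start = as.Date(index_start), index_end = as.Date(index_end))
}

# Birth date giving exactly `age` completed years at index_date.
birth_for_age <- function(index_date, age) {
  y <- as.integer(format(index_date, "%Y")) - age
  b <- as.Date(paste0(y, format(index_date, "-%m-%d")), optional = TRUE)
  if (is.na(b)) b <- as.Date(paste0(y, "-02-28"))  # Feb 29 anniversary
  b <- b - 120
  while (age_at(b, index_date) != age) {
    b <- b + ifelse(age_at(b, index_date) > age, 1L, -1L)
  }
  b
}

sample1 <- function(x, ...) x[[sample.int(length(x), 1, ...)]]

# Script attribute templates per planted ground-truth (label, step).
make_script <- function(pid, date, truth_label, step) {
  tmpl <- if (truth_label == "long_term") {
    if (step == "instruction") {
      list("prednisolone", 5, 28, "one tablet daily long term")
    } else {
      list("prednisolone", 5, 56, "take 2 tablets daily")  # 10 mg/day
    }
  } else {
    switch(step,
      instruction = sample1(list(
        list("prednisolone", 5, 40, "take 8 tablets daily for 5 days then stop"),
        list("prednisolone", 5, 30, "6 tablets daily reducing dose"),
        list("prednisolone", 5, 56, "short course: 40 mg daily for 7 days"))),
      dose = sample1(list(
        list("prednisolone", 5, 40, "take 8 tablets daily"),      # 40 mg/day
        list("dexamethasone", 2, 15, "take 3 tablets daily"))),   # 40 pred-eq
      list("prednisolone", 5, 28, "use as directed"))  # event / annual_count
  }
  data.table::data.table(
    patient_id = pid, date = date, drug = tmpl[[1]],
    strength_mg_per_unit = tmpl[[2]], quantity_units = tmpl[[3]],
    instruction_text = tmpl[[4]],
    therapy_class = "OCS")
}

controller_scripts <- function(pid, index_date, gina_step) {
  dts <- function(k) index_date - sample(30:360, k, replace = TRUE)
  row <- function(drug, class, k = 1) {
    data.table::data.table(patient_id = pid, date = dts(k), drug = drug,
                           strength_mg_per_unit = NA_real_, quantity_units = 1,
                           instruction_text = "", therapy_class = class)
  }
  switch(gina_step,
    none = NULL,
    `1` = NULL,
    `2` = row("budesonide_low", "ICS", 2),
    `3` = if (stats::runif(1) < 0.5) {
      row("budesonide_formoterol_low", "ICS_LABA", 2)
    } else {
      rbind(row("budesonide_low", "ICS", 1), row("montelukast", "LTRA", 1))
    },
    `4` = row(sample1(c("budesonide_formoterol_medium",
                        "fluticasone_salmeterol_high")), "ICS_LABA", 2),
    `5` = rbind(row("fluticasone_salmeterol_high", "ICS_LABA", 2),
                row("omalizumab", "biologic", 1)))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces the three EHR-style tables plus ground-truth tables recording
#' each patient's intended eligibility, arm, stratifiers, pattern labels and
#' per-script classification. In strict mode every planted quantity sits
#' strictly inside its decisive region, so the full pipeline recovers the
#' ground truth exactly.
#'
#' @param config [simulation_config()].
#' @return List of data.tables `patients`, `prescriptions`, `events`,
#'   `truth_patients`, `truth_scripts`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  set.seed(config$seed)
  n <- config$n_patients
  inel <- config$ineligible
  roles <- c("eligible", "non_ocs", names(inel))
  probs <- c(1 - config$prop_non_ocs - sum(inel), config$prop_non_ocs, inel)
  role <- sample(roles, n, replace = TRUE, prob = probs)
  lab_map <- label_category_map()
  ranges <- gap_sampling_ranges(config$strict_gaps)
  index_days <- as.integer(config$index_end - config$index_start)

  pat_rows <- vector("list", n)
  rx_rows <- vector("list", n)
  ev_rows <- vector("list", n)
  tp_rows <- vector("list", n)
  ts_rows <- vector("list", n)

  ev_row <- function(pid, date, category) {
    data.table::data.table(patient_id = pid, date = date, category = category)
  }

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    r <- role[i]
    index <- config$index_start + sample.int(index_days + 1, 1) - 1L
    age <- switch(r,
      age = sample(1:3, 1),
      excl_adult = , non_ocs = sample(18:80, 1),
      excl_minor = sample(4:17, 1),
      {
        band <- sample1(names(config$age_mixture), prob = config$age_mixture)
        switch(band, child = sample(4:11, 1), adolescent = sample(12:17, 1),
               adult = sample(18:80, 1))
      })
    birth <- birth_for_age(index, age)
    reg_start <- index - if (r == "baseline") sample(30:300, 1) else
      sample(430:2500, 1)
    if (reg_start < birth) reg_start <- birth
    sex <- sample1(c("male", "female"), prob = c(0.443, 0.557))

    rx <- list()
    ev <- list()
    ts <- NULL
    n_rx <- 0L
    detailed <- NA_character_
    simplified <- NA_character_
    n_courses <- NA_integer_
    use <- NA_character_
    gina <- NA_character_
    saba <- NA_character_

    if (r == "non_ocs") {
      ref <- reg_start + 365L
      ev <- c(ev, list(ev_row(pid, ref + sample(-30:30, 1), "asthma_consultation")))
      last_date <- ref
      index <- ref  # reference date for records below
    } else {
      # pattern and course dates
      detailed0 <- sample1(names(config$pattern_mixture),
                           prob = config$pattern_mixture)
      cats <- lab_map[[detailed0]]
      gaps <- integer(0)
      if (length(cats)) {
        extra <- stats::rpois(1, 0.8)
        gap_cats <- c(cats, if (extra) sample(cats, extra, replace = TRUE))
        gap_cats <- sample(gap_cats)  # shuffle order along the timeline
        gaps <- vapply(gap_cats, function(cc) sample1(ranges[[cc]]), integer(1))
      }
      course_dates <- index + cumsum(c(0L, gaps))
      n_rx <- length(course_dates)

      long_term_patient <- r == "eligible" &&
        stats::runif(1) < config$prop_long_term
      steps <- sample(names(config$step_mixture), n_rx, replace = TRUE,
                      prob = config$step_mixture)
      ann <- which(steps == "annual_count")
      if (length(ann) > 2) steps[ann[-(1:2)]] <- "dose"
      labels <- rep("intermittent", n_rx)
      if (long_term_patient) {
        j <- sample.int(n_rx, 1)
        labels[j] <- "long_term"
        steps[j] <- sample1(c("instruction", "dose"))
      }
      for (k in seq_len(n_rx)) {
        rx <- c(rx, list(make_script(pid, course_dates[k], labels[k], steps[k])))
        if (labels[k] == "intermittent" && steps[k] == "concurrent_event") {
          ev <- c(ev, list(ev_row(pid, course_dates[k] + sample(-5:5, 1),
                                  sample1(c("lrti", "exacerbation")))))
        }
      }
      ts <- data.table::data.table(patient_id = pid, date = course_dates,
                                   truth_label = labels, truth_step = steps)
      if (r != "no_asthma") {
        ev <- c(ev, list(ev_row(pid, index + sample(-60:60, 1),
                                sample1(c("asthma_diagnosis",
                                          "asthma_consultation")))))
      }
      if (r == "excl_adult") {
        cond <- sample1(exclusion_conditions())
        ev <- c(ev, list(ev_row(pid, index - sample(0:300, 1),
                                paste0("exclusion_condition:", cond))))
      }
      if (r == "excl_minor") {
        cond <- sample1(exclusion_conditions())
        ev <- c(ev, list(ev_row(pid, course_dates[1] + sample(-30:30, 1),
                                paste0("exclusion_condition:", cond))))
      }
      # baseline therapy and stratifier ground truth (eligible patients only)
      if (r == "eligible") {
        gina <- sample1(names(config$gina_mixture), prob = config$gina_mixture)
        saba <- if (gina == "none") "0" else if (gina == "1") {
          sample1(c("1-2", ">=3"),
                  prob = config$saba_mixture[c("1-2", ">=3")])
        } else {
          sample1(names(config$saba_mixture), prob = config$saba_mixture)
        }
        ctrl <- controller_scripts(pid, index, gina)
        if (!is.null(ctrl)) rx <- c(rx, list(ctrl))
        fills <- switch(saba, `0` = 0L, `1-2` = sample(1:2, 1),
                        `>=3` = sample(3:6, 1))
        if (fills > 0) {
          rx <- c(rx, list(data.table::data.table(
            patient_id = pid, date = index - sample(1:365, fills),
            drug = "salbutamol", strength_mg_per_unit = NA_real_,
            quantity_units = 1, instruction_text = "",
            therapy_class = "SABA")))
        }
        use <- if (long_term_patient) "any_long_term" else "intermittent_only"
        if (!long_term_patient) {
          detailed <- detailed0
          n_courses <- n_rx
          simplified <- simplify_label(n_rx, cats)
        }
      }
      last_date <- max(course_dates)
    }

    reg_end <- last_date + sample(30:400, 1)
    pat_rows[[i]] <- data.table::data.table(
      patient_id = pid, sex = sex, birth_date = birth,
      registration_start = reg_start, registration_end = reg_end)
    eligible <- r %in% c("eligible", "non_ocs")
    reason <- switch(r, age = "age_below_minimum",
                     no_asthma = "no_concurrent_asthma_event",
                     baseline = "insufficient_baseline",
                     excl_adult = , excl_minor = "exclusion_condition",
                     "none")
    tp_rows[[i]] <- data.table::data.table(
      patient_id = pid, role = r,
      arm = if (r == "non_ocs") "non_ocs" else "ocs",
      eligible = eligible, exclusion_reason = reason,
      index_date = index, age = age,
      age_band = if (eligible && r != "non_ocs") age_band(age) else NA_character_,
      gina_step = gina, saba_band = saba, patient_use = use,
      n_prescriptions = n_rx, n_courses = n_courses,
      detailed_label = detailed, simplified_label = simplified)
    rx_rows[[i]] <- if (length(rx)) data.table::rbindlist(rx) else NULL
    ev_rows[[i]] <- if (length(ev)) data.table::rbindlist(ev) else NULL
    ts_rows[[i]] <- ts
  }

  list(patients = data.table::rbindlist(pat_rows),
       prescriptions = data.table::rbindlist(rx_rows),
       events = data.table::rbindlist(ev_rows),
       truth_patients = data.table::rbindlist(tp_rows),
       truth_scripts = data.table::rbindlist(ts_rows))
}

#' Hand-written boundary fixture cohort
#'
#' A small fixed cohort exercising every rule boundary: gaps of exactly
#' 89/90/181/182/364/365 days, same-day duplicate scripts, ages 3/4/11/12/
#' 17/18 at index, an asthma event exactly at the concurrency-window edge
#' (and one just outside), each chronic exclusion condition once in an
#' adult, and a minor with a condition distant from versus concurrent with
#' OCS.
#'
#' @return List of data.tables `patients`, `prescriptions`, `events` and
#'   `expectations` (`patient_id`, `check`, `expected`).
#' @export
make_boundary_fixtures <- function() {
  index <- as.Date("2012-06-01")
  pat <- list(); rx <- list(); ev <- list(); exp <- list()
  intermit <- "take 8 tablets daily for 5 days then stop"
  add_patient <- function(pid, age, scripts_offsets, event_offset = 10,
                          extra_events = NULL, check = NULL, expected = NULL,
                          reg_start_offset = -800) {
    pat[[length(pat) + 1]] <<- data.table::data.table(
      patient_id = pid, sex = "female",
      birth_date = birth_for_age(index, age),
      registration_start = index + reg_start_offset,
      registration_end = index + max(scripts_offsets, 0) + 200)
    rx[[length(rx) + 1]] <<- data.table::data.table(
      patient_id = pid, date = index + scripts_offsets, drug = "prednisolone",
      strength_mg_per_unit = 5, quantity_units = 40,
      instruction_text = intermit, therapy_class = "OCS")
    ev[[length(ev) + 1]] <<- data.table::data.table(
      patient_id = pid, date = index + event_offset,
      category = "asthma_diagnosis")
    if (!is.null(extra_events)) ev[[length(ev) + 1]] <<- extra_events
    if (!is.null(check)) {
      exp[[length(exp) + 1]] <<- data.table::data.table(
        patient_id = pid, check = check, expected = expected)
    }
  }
  gap_expect <- c(`89` = "Frequent only", `90` = "Moderately frequent only",
                  `181` = "Moderately frequent only", `182` = "Infrequent only",
                  `364` = "Infrequent only", `365` = "Sporadic")
  for (g in names(gap_expect)) {
    add_patient(paste0("GAP", g), 30, c(0L, as.integer(g)),
                check = "detailed_label", expected = gap_expect[[g]])
  }
  add_patient("DUP", 30, c(0L, 0L, 40L), check = "detailed_label",
              expected = "Frequent only")
  for (a in c(3, 4, 11, 12, 17, 18)) {
    add_patient(paste0("AGE", a), a, 0L, check = "age_band",
                expected = if (a < 4) "excluded:age_below_minimum"
                else age_band(a))
  }
  add_patient("EVT91", 30, 0L, event_offset = 91, check = "eligible",
              expected = "TRUE")
  add_patient("EVT92", 30, 0L, event_offset = 92, check = "eligible",
              expected = "FALSE")
  for (cond in exclusion_conditions()) {
    add_patient(paste0("EXC_", toupper(substr(cond, 1, 6))), 45, 0L,
                extra_events = data.table::data.table(
                  patient_id = paste0("EXC_", toupper(substr(cond, 1, 6))),
                  date = index - 400,
                  category = paste0("exclusion_condition:", cond)),
                check = "eligible", expected = "FALSE",
                reg_start_offset = -800)
  }
  add_patient("MIN_FAR", 10, 0L,
              extra_events = data.table::data.table(
                patient_id = "MIN_FAR", date = index - 700,
                category = "exclusion_condition:ulcerative_colitis"),
              check = "eligible", expected = "TRUE",
              reg_start_offset = -900)
  add_patient("MIN_NEAR", 10, 0L,
              extra_events = data.table::data.table(
                patient_id = "MIN_NEAR", date = index + 30,
                category = "exclusion_condition:ulcerative_colitis"),
              check = "eligible", expected = "FALSE")
  list(patients = data.table::rbindlist(pat),
       prescriptions = data.table::rbindlist(rx),
       events = data.table::rbindlist(ev),
       expectations = data.table::rbindlist(exp))
}
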