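# Domain model: typed readers for the three EHR-style tables, the WHO
# ATC/DDD-derived dose table, and per-script daily-dose arithmetic.

#' Controlled vocabularies for the EHR tables
#'
#' @return `therapy_classes()`: character vector of recognised prescription
#'   therapy classes. `event_categories()`: recognised clinical event
#'   categories, including one `exclusion_condition:<name>` entry per chronic
#'   condition in [exclusion_conditions()]. `asthma_therapy_classes()`: the
#'   subset of therapy classes that count as asthma medication when looking
#'   for a concurrent asthma event.
#' @export
therapy_classes <- function() {
  c("OCS", "SABA", "ICS", "ICS_LABA", "LTRA", "LAMA", "biologic", "other")
}

#' @rdname therapy_classes
#' @export
asthma_therapy_classes <- function() {
  c("SABA", "ICS", "ICS_LABA", "LTRA", "LAMA", "biologic")
}

#' Chronic conditions that exclude OCS-treated patients
#'
#' Systemic conditions commonly managed with long-term oral corticosteroids;
#' their presence makes OCS prescriptions unattributable to asthma.
#'
#' @return Character vector of condition identifiers.
#' @export
exclusion_conditions <- function() {
  c("ankylosing_spondylitis", "sjogren_syndrome",
    "systemic_lupus_erythematosus", "temporal_arteritis",
    "ulcerative_colitis", "psoriatic_arthritis", "multiple_sclerosis",
    "polymyalgia_rheumatica", "crohn_disease", "respiratory_cancer")
}

#' @rdname therapy_classes
#' @export
event_categories <- function() {
  c("asthma_diagnosis", "asthma_consultation", "lrti", "exacerbation",
    paste0("exclusion_condition:", exclusion_conditions()))
}

# Canonical column sets, in file order. "!" prefix marks mandatory presence
# of the column; value-level requirements are enforced row-wise.
ehr_schema <- function() {
  list(
    patients = c("patient_id", "sex", "birth_date", "registration_start",
                 "registration_end"),
    prescriptions = c("patient_id", "date", "drug", "strength_mg_per_unit",
                      "quantity_units", "instruction_text", "therapy_class"),
    events = c("patient_id", "date", "category")
  )
}

parse_date_col <- function(x, date_format = c("iso", "dayfirst")) {
  date_format <- match.arg(date_format)
  fmt <- if (date_format == "iso") "%Y-%m-%d" else "%d/%m/%Y"
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & nzchar(trimws(x))
  out[ok] <- as.Date(trimws(x[ok]), format = fmt, optional = TRUE)
  out
}

# Read one delimited table, remap columns, coerce types, and collect
# row-level failures instead of dropping them.
read_ehr_table <- function(path, table = c("patients", "prescriptions", "events"),
                           colmap = NULL, date_format = "iso") {
  table <- match.arg(table)
  wanted <- ehr_schema()[[table]]
  raw <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  for (col in names(raw)) {  # quoted empty fields arrive as "" rather than NA
    blank <- which(!is.na(raw[[col]]) & !nzchar(trimws(raw[[col]])))
    if (length(blank)) data.table::set(raw, i = blank, j = col,
                                       value = NA_character_)
  }
  if (!is.null(colmap)) {
    for (canon in names(colmap)) {
      src <- colmap[[canon]]
      if (src %in% names(raw)) data.table::setnames(raw, src, canon)
    }
  }
  optional <- c("registration_end", "strength_mg_per_unit", "quantity_units",
                "instruction_text")
  missing_cols <- setdiff(setdiff(wanted, optional), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("schema error in %s table: missing column(s) %s", table,
                 paste(sQuote(missing_cols), collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(wanted, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[, wanted, with = FALSE]
  n_in <- nrow(raw)
  reject_reason <- rep(NA_character_, n_in)
  flag <- function(bad, why) {
    new <- bad & is.na(reject_reason)
    reject_reason[new] <<- why
  }

  flag(is.na(raw$patient_id) | !nzchar(raw$patient_id), "missing patient_id")
  date_cols <- switch(table,
    patients = c("birth_date", "registration_start", "registration_end"),
    prescriptions = "date",
    events = "date")
  parsed_dates <- lapply(date_cols, function(cl) parse_date_col(raw[[cl]], date_format))
  names(parsed_dates) <- date_cols
  for (cl in date_cols) {
    required <- cl != "registration_end"
    bad <- is.na(parsed_dates[[cl]]) & (required | !is.na(raw[[cl]]))
    flag(bad, sprintf("unparseable date in %s", cl))
  }
  if (table == "patients") {
    sex <- tolower(raw$sex)
    flag(!is.na(sex) & !sex %in% c("male", "female", "unknown"), "invalid sex")
    flag(!is.na(parsed_dates$registration_end) &
           parsed_dates$registration_start > parsed_dates$registration_end,
         "registration_start after registration_end")
    flag(parsed_dates$birth_date > parsed_dates$registration_start,
         "birth_date after registration_start")
  }
  if (table == "prescriptions") {
    strength <- suppressWarnings(as.numeric(raw$strength_mg_per_unit))
    quantity <- suppressWarnings(as.numeric(raw$quantity_units))
    flag(!is.na(raw$strength_mg_per_unit) & (is.na(strength) | strength < 0),
         "invalid strength_mg_per_unit")
    flag(!is.na(raw$quantity_units) & (is.na(quantity) | quantity <= 0),
         "invalid quantity_units")
    flag(!raw$therapy_class %in% therapy_classes(), "unknown therapy_class")
    flag(raw$therapy_class == "OCS" & is.na(strength),
         "OCS prescription without strength")
  }
  if (table == "events") {
    flag(!raw$category %in% event_categories(), "unknown event category")
  }

  keep <- is.na(reject_reason)
  rejects <- data.table::data.table(
    table = table, row = which(!keep),
    patient_id = raw$patient_id[!keep], reason = reject_reason[!keep])
  rec <- raw[keep]
  for (cl in date_cols) data.table::set(rec, j = cl, value = parsed_dates[[cl]][keep])
  if (table == "patients") rec[, sex := tolower(sex)]
  if (table == "prescriptions") {
    rec[, strength_mg_per_unit := suppressWarnings(as.numeric(strength_mg_per_unit))]
    rec[, quantity_units := suppressWarnings(as.numeric(quantity_units))]
    rec[is.na(instruction_text), instruction_text := ""]
  }
  list(records = rec[], rejects = rejects)
}

#' Read the patients, prescriptions and events tables
#'
#' Reads the three delimited input tables, applies optional column-name
#' remapping, coerces types, and collects rows that fail coercion into a
#' rejects table (with a reason per row) rather than dropping them silently.
#' A missing mandatory column raises a schema error naming the column.
#'
#' @param patients_file,prescriptions_file,events_file Paths to CSV files.
#' @param colmap Optional named list of per-table column maps, e.g.
#'   `list(patients = c(patient_id = "pid"))`, mapping canonical names to
#'   source column names.
#' @param date_format `"iso"` (default, `YYYY-MM-DD`) or `"dayfirst"`
#'   (`DD/MM/YYYY`). Ambiguous day-first dates are never guessed.
#' @return List with data.tables `patients`, `prescriptions`, `events` and
#'   `rejects` (columns `table`, `row`, `patient_id`, `reason`). For every
#'   table, accepted rows + rejected rows equal the input row count.
#' @export
read_ehr_tables <- function(patients_file, prescriptions_file, events_file,
                            colmap = NULL, date_format = "iso") {
  pr <- read_ehr_table(patients_file, "patients", colmap$patients, date_format)
  rx <- read_ehr_table(prescriptions_file, "prescriptions", colmap$prescriptions,
                       date_format)
  ev <- read_ehr_table(events_file, "events", colmap$events, date_format)
  list(patients = pr$records, prescriptions = rx$records, events = ev$records,
       rejects = data.table::rbindlist(list(pr$rejects, rx$rejects, ev$rejects)))
}

#' Write normalized EHR tables to a directory
#'
#' @param tables List as returned by [read_ehr_tables()] or
#'   [simulate_cohort()]; every data.table element is written as
#'   `<name>.csv`.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_ehr_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    if (!is.data.frame(tables[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(tables[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Defined daily doses for oral systemic glucocorticoids
#'
#' The bundled WHO ATC/DDD-derived table for oral H02AB substances. The DDD
#' anchors prednisolone-equivalence: prednisolone's DDD is 10 mg.
#'
#' @param path Optional path to an alternative table with columns
#'   `substance`, `ddd_mg`.
#' @return data.table with columns `substance`, `atc_code`, `ddd_mg`, `route`.
#' @export
ddd_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ddd_h02ab.csv", package = "ocspatterns")
  }
  dt <- data.table::fread(path)
  stopifnot(all(dt$ddd_mg > 0), "prednisolone" %in% dt$substance)
  dt
}

#' Convert a corticosteroid daily dose to prednisolone equivalents
#'
#' Uses the ratio of defined daily doses:
#' `dose * DDD(prednisolone) / DDD(substance)`.
#'
#' @param drug Character vector of substance names (case-insensitive).
#' @param daily_dose_mg Non-negative numeric vector of daily doses in mg.
#' @param ddd DDD lookup table, defaults to the bundled [ddd_table()].
#' @return Numeric vector of prednisolone-equivalent mg/day.
#' @export
#' @examples
#' to_prednisolone_equivalent("prednisolone", 40)  # 40
#' to_prednisolone_equivalent("dexamethasone", 1.5)  # 10
to_prednisolone_equivalent <- function(drug, daily_dose_mg, ddd = ddd_table()) {
  if (any(daily_dose_mg < 0, na.rm = TRUE)) {
    stop("daily_dose_mg must be non-negative", call. = FALSE)
  }
  idx <- match(tolower(drug), tolower(ddd$substance))
  if (anyNA(idx[!is.na(drug)])) {
    unknown <- unique(drug[is.na(idx) & !is.na(drug)])
    stop(sprintf("unknown substance(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  pred_ddd <- ddd$ddd_mg[match("prednisolone", tolower(ddd$substance))]
  daily_dose_mg * pred_ddd / ddd$ddd_mg[idx]
}

word_numbers <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
                  seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11,
                  twelve = 12)

as_count <- function(tok) {
  n <- suppressWarnings(as.numeric(tok))
  ifelse(is.na(n), unname(word_numbers[tolower(tok)]), n)
}

num_re <- paste0("([0-9]+(?:\\.[0-9]+)?|", paste(names(word_numbers), collapse = "|"), ")")

extract_first <- function(text, re) {
  m <- regmatches(text, regexec(re, text, ignore.case = TRUE, perl = TRUE))
  vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_, character(1))
}

#' Parse a free-text dosing instruction
#'
#' Rule-based extraction of the quantities needed for daily-dose arithmetic:
#' tablet units per day, an explicit mg-per-day amount, and a course
#' duration in days. Unrecognised text yields `NA`s; parsing never raises.
#'
#' @param text Character vector of dosing instructions.
#' @return data.table with columns `units_per_day`, `mg_per_day`,
#'   `duration_days` (all numeric, `NA` where absent).
#' @export
#' @examples
#' parse_dosing_instruction("take six tablets daily for 5 days then stop")
parse_dosing_instruction <- function(text) {
  text <- ifelse(is.na(text), "", tolower(text))
  daily_re <- "(?:daily|once daily|a day|per day|each day|every day)"
  units <- as_count(extract_first(
    text, paste0(num_re, "\\s*(?:tab(?:let)?s?)?\\s*", daily_re)))
  mg <- as_count(extract_first(
    text, paste0(num_re, "\\s*mg\\s*", daily_re)))
  # "6 tablets daily" should not also match the mg pattern and vice versa
  has_mg <- grepl(paste0(num_re, "\\s*mg"), text, ignore.case = TRUE)
  units[has_mg] <- NA_real_
  mg[!has_mg] <- NA_real_
  duration <- as_count(extract_first(
    text, paste0("for\\s+", num_re, "\\s+days?")))
  duration2 <- as_count(extract_first(text, paste0(num_re, "[- ]day course")))
  duration <- ifelse(is.na(duration), duration2, duration)
  data.table::data.table(units_per_day = units, mg_per_day = mg,
                         duration_days = duration)
}

#' Daily dose of an OCS prescription in mg/day
#'
#' Stepwise, most-definitive-first arithmetic: an explicit mg/day in the
#' instruction wins; else tablet units/day times tablet strength; else, when
#' the dispensed quantity and a parsed course duration are available,
#' `strength * quantity / duration`. Otherwise the dose is unknown (`NA`).
#'
#' @param strength_mg_per_unit Tablet strength in mg (numeric vector).
#' @param quantity_units Dispensed units (numeric vector, `NA` if unknown).
#' @param instruction_text Free-text dosing instruction.
#' @return Numeric vector of mg/day, `NA` where undeterminable.
#' @export
#' @examples
#' daily_dose_from_script(5, NA, "8 tablets daily")      # 40
#' daily_dose_from_script(5, 40, "for 5 days")           # 40
daily_dose_from_script <- function(strength_mg_per_unit, quantity_units,
                                   instruction_text) {
  p <- parse_dosing_instruction(instruction_text)
  dose <- p$mg_per_day
  via_units <- is.na(dose) & !is.na(p$units_per_day) & !is.na(strength_mg_per_unit)
  dose[via_units] <- strength_mg_per_unit[via_units] * p$units_per_day[via_units]
  via_qty <- is.na(dose) & !is.na(quantity_units) & !is.na(p$duration_days) &
    !is.na(strength_mg_per_unit) & p$duration_days > 0
  dose[via_qty] <- strength_mg_per_unit[via_qty] * quantity_units[via_qty] /
    p$duration_days[via_qty]
  if (any(dose < 0, na.rm = TRUE)) {
    stop("negative daily dose computed; invalid prescription record",
         call. = FALSE)
  }
  dose
}

# Completed years of age at `date`, birthday-exact.
age_at <- function(birth_date, date) {
  b <- as.POSIXlt(birth_date)
  d <- as.POSIXlt(date)
  before_birthday <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  (d$year - b$year) - as.integer(before_birthday)
}
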