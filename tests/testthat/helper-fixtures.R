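# Shared fixture builders: tiny in-code cohorts written to temp CSVs.

library(data.table)

fixture_patients <- function() {
  data.table(
    patient_id = c("A", "B", "C"),
    sex = c("male", "female", "female"),
    birth_date = c("1980-03-15", "2001-07-01", "1975-01-01"),
    registration_start = c("2005-01-01", "2008-06-01", "2006-01-01"),
    registration_end = c("2018-12-31", "2019-12-31", ""))
}

fixture_prescriptions <- function() {
  data.table(
    patient_id = c("A", "A", "B"),
    date = c("2010-05-01", "2010-06-01", "2011-02-01"),
    drug = c("prednisolone", "prednisolone", "salbutamol"),
    strength_mg_per_unit = c(5, 5, NA),
    quantity_units = c(40, 40, 1),
    instruction_text = c("take 8 tablets daily for 5 days then stop", "", ""),
    therapy_class = c("OCS", "OCS", "SABA"))
}

fixture_events <- function() {
  data.table(
    patient_id = c("A", "B"),
    date = c("2010-05-10", "2011-02-10"),
    category = c("asthma_diagnosis", "asthma_consultation"))
}

write_fixture_csvs <- function(dir = tempfile(),
                               patients = fixture_patients(),
                               prescriptions = fixture_prescriptions(),
                               events = fixture_events()) {
  dir.create(dir, showWarnings = FALSE)
  paths <- list(patients = file.path(dir, "patients.csv"),
                prescriptions = file.path(dir, "prescriptions.csv"),
                events = file.path(dir, "events.csv"))
  fwrite(patients, paths$patients)
  fwrite(prescriptions, paths$prescriptions)
  fwrite(events, paths$events)
  paths
}

# One patient's prescriptions table, OCS rows only, from dates + per-script
# attributes.
ocs_scripts <- function(dates, strength = 5, quantity = NA_real_,
                        instruction = "", drug = "prednisolone",
                        patient_id = "P1") {
  data.table(patient_id = patient_id, date = as.Date(dates), drug = drug,
             strength_mg_per_unit = strength, quantity_units = quantity,
             instruction_text = instruction, therapy_class = "OCS")
}

empty_events <- function() {
  data.table(patient_id = character(0), date = as.Date(character(0)),
             category = character(0))
}
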