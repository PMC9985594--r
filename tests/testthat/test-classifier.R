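test_that("instruction rulebook resolves taper, maintenance and empty text", {
  rb <- default_rulebook()
  expect_equal(parse_instruction("take six tablets daily for 5 days then stop", rb),
               "intermittent")
  expect_equal(parse_instruction("one daily long term", rb), "long_term")
  expect_equal(parse_instruction("", rb), "undecided")
  expect_equal(parse_instruction("take with food", rb), "undecided")
  # first matching rule wins: maintenance phrases rank before course phrases
  expect_equal(parse_instruction("long term, review in 30 days", rb), "long_term")
})

test_that("dose thresholds split acute, maintenance and indeterminate", {
  cfg <- classifier_config()
  expect_equal(classify_by_dose(40, cfg), "intermittent")
  expect_equal(classify_by_dose(20, cfg), "intermittent")   # at threshold
  expect_equal(classify_by_dose(5, cfg), "long_term")
  expect_equal(classify_by_dose(10, cfg), "long_term")      # at threshold
  expect_equal(classify_by_dose(15, cfg), "undecided")
  expect_equal(classify_by_dose(NA_real_, cfg), "undecided")
  expect_error(classify_by_dose(-1, cfg), "negative")
})

test_that("concurrent LRTI/exacerbation marks scripts intermittent", {
  ev <- data.table(patient_id = "P1", date = as.Date("2010-05-04"),
                   category = "exacerbation")
  expect_equal(classify_by_concurrent_event(as.Date("2010-05-07"), ev, 14),
               "intermittent")
  expect_equal(classify_by_concurrent_event(as.Date("2010-07-06"), ev, 14),
               "undecided")
  expect_equal(classify_by_concurrent_event(as.Date("2010-05-07"),
                                            empty_events(), 14),
               "undecided")
})

test_that("annual count labels by trailing 365-day window (hand oracle)", {
  expect_equal(classify_by_annual_count(as.Date("2010-01-01"), 2),
               "intermittent")
  # 3 scripts spread over >1 year: windows hold 1, 2, 2 scripts
  d3 <- as.Date(c("2010-01-01", "2010-07-01", "2011-02-01"))
  expect_equal(classify_by_annual_count(d3, 2),
               rep("intermittent", 3))
  # 6 scripts inside one year: trailing counts 1..6, so 3rd+ are long_term
  d6 <- as.Date("2010-01-01") + seq(0, 300, by = 60)
  expect_equal(classify_by_annual_count(d6, 2),
               c("intermittent", "intermittent", rep("long_term", 4)))
  expect_equal(classify_by_annual_count(as.Date(character(0)), 2),
               character(0))
})

test_that("classify_patient chains steps and derives patient-level use", {
  ev <- empty_events()
  taper <- ocs_scripts(c("2010-01-01", "2010-04-01", "2011-01-01"),
                       instruction = "take 8 tablets daily for 5 days then stop")
  res <- classify_patient(taper, ev)
  expect_equal(res$scripts$label, rep("intermittent", 3))
  expect_equal(res$scripts$decision_step, rep("instruction", 3))
  expect_equal(res$patient_use, "intermittent_only")

  mixedrx <- rbind(
    ocs_scripts("2010-01-01", instruction = "take one tablet daily"),  # 5 mg
    ocs_scripts("2010-06-01", instruction = "take 8 tablets daily"))   # 40 mg
  res <- classify_patient(mixedrx, ev)
  expect_equal(res$scripts$label, c("long_term", "intermittent"))
  expect_equal(res$scripts$decision_step, c("dose", "dose"))
  expect_equal(res$patient_use, "any_long_term")

  expect_error(classify_patient(ocs_scripts(character(0)), ev), "no OCS")
})

test_that("decision step records the earliest decisive step", {
  ev <- data.table(patient_id = "P1", date = as.Date("2010-01-03"),
                   category = "lrti")
  rx <- rbind(
    ocs_scripts("2010-01-01", instruction = "use as directed"),  # event step
    ocs_scripts("2010-09-01", instruction = "use as directed"),  # annual step
    ocs_scripts("2011-08-01", instruction = "short course of 8 tablets daily"))
  res <- classify_patient(rx, ev)
  expect_equal(res$scripts$decision_step,
               c("concurrent_event", "annual_count", "instruction"))
  expect_equal(res$scripts$label, rep("intermittent", 3))
})

test_that("unknown substance or unparseable dose skips the dose step", {
  rx <- ocs_scripts("2010-01-01", instruction = "take 8 tablets daily",
                    drug = "mysterysteroid")
  res <- classify_patient(rx, empty_events())
  expect_equal(res$scripts$decision_step, "annual_count")
  expect_true(is.na(res$scripts$pred_equiv_mg_per_day))
})

test_that("earlier steps shadow later ones when thresholds tighten", {
  # a script decided at the instruction step keeps its label no matter how
  # aggressive the dose thresholds become
  rx <- ocs_scripts("2010-01-01", quantity = 10,
                    instruction = "2 tablets daily for 5 days then stop")
  loose <- classify_patient(rx, empty_events(), classifier_config())
  tight <- classify_patient(rx, empty_events(),
                            classifier_config(dose_high_mg = 100,
                                              dose_low_mg = 99))
  expect_equal(loose$scripts$label, "intermittent")
  expect_equal(tight$scripts$label, "intermittent")
  expect_equal(tight$scripts$decision_step, "instruction")
})

test_that("labels are deterministic and order-invariant", {
  set.seed(8)
  dates <- as.Date("2010-01-01") + sample(0:900, 6)
  rx <- ocs_scripts(dates, instruction = "use as directed")
  ev <- data.table(patient_id = "P1", date = dates[2] + 3, category = "lrti")
  res1 <- classify_patient(rx, ev)
  res2 <- classify_patient(rx[sample(.N)], ev)
  expect_equal(res1$scripts, res2$scripts)
})

test_that("classify_cohort labels every OCS script of eligible patients", {
  sim <- simulate_cohort(simulation_config(n_patients = 50, seed = 21))
  cb <- build_cohort(sim$patients, sim$prescriptions, sim$events)
  cls <- classify_cohort(cb$cohort, sim$prescriptions, sim$events)
  elig <- cb$cohort[eligible == TRUE & arm == "ocs", patient_id]
  n_ocs <- nrow(sim$prescriptions[therapy_class == "OCS" & patient_id %in% elig])
  expect_equal(nrow(cls$scripts), n_ocs)
  expect_true(all(cls$scripts$label %in% c("intermittent", "long_term")))
  expect_true(all(cls$scripts$decision_step %in%
                    c("instruction", "dose", "concurrent_event", "annual_count")))
})
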