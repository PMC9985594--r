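one_patient <- function(birth = "1980-01-01", reg_start = "2005-01-01",
                        reg_end = "2020-01-01", id = "P1") {
  data.table(patient_id = id, sex = "female", birth_date = as.Date(birth),
             registration_start = as.Date(reg_start),
             registration_end = as.Date(reg_end))
}

asthma_event <- function(date, id = "P1", category = "asthma_diagnosis") {
  data.table(patient_id = id, date = as.Date(date), category = category)
}

test_that("index date is the earliest OCS prescription", {
  rx <- ocs_scripts(c("2010-06-01", "2010-05-01"))
  expect_equal(find_index_date(rx), as.Date("2010-05-01"))
  expect_equal(find_index_date(ocs_scripts("2012-01-01")), as.Date("2012-01-01"))
  saba <- copy(rx)[, therapy_class := "SABA"]
  expect_true(is.na(find_index_date(saba)))
})

test_that("inclusion rules fail in fixed order with named reasons", {
  idx <- as.Date("2010-05-01")
  rx <- ocs_scripts(idx)
  ok <- check_inclusion(one_patient(), idx, asthma_event("2010-05-11"), rx)
  expect_true(ok$eligible)

  young <- check_inclusion(one_patient(birth = "2007-01-01"), idx,
                           asthma_event("2010-05-11"), rx)
  expect_false(young$eligible)
  expect_equal(young$reason, "age_below_minimum")

  far <- check_inclusion(one_patient(), idx, asthma_event("2010-11-17"), rx)
  expect_false(far$eligible)
  expect_equal(far$reason, "no_concurrent_asthma_event")

  short <- check_inclusion(one_patient(reg_start = "2010-01-01"), idx,
                           asthma_event("2010-05-11"), rx)
  expect_false(short$eligible)
  expect_equal(short$reason, "insufficient_baseline")
})

test_that("asthma-therapy prescriptions count as concurrent asthma events", {
  idx <- as.Date("2010-05-01")
  rx <- rbind(ocs_scripts(idx),
              ocs_scripts("2010-04-20")[, therapy_class := "SABA"])
  res <- check_inclusion(one_patient(), idx, empty_events(), rx)
  expect_true(res$eligible)
})

test_that("chronic-condition exclusion differs for adults and minors", {
  crohn <- asthma_event("2007-03-01", category = "exclusion_condition:crohn_disease")
  adult <- check_exclusion_conditions(crohn, 40, as.Date("2010-05-01"))
  expect_true(adult$excluded)
  expect_equal(adult$condition, "crohn_disease")

  colitis <- asthma_event("2007-05-01",
                          category = "exclusion_condition:ulcerative_colitis")
  minor <- check_exclusion_conditions(colitis, 10, as.Date("2010-05-01"))
  expect_false(minor$excluded)  # 3 years from any OCS: not concurrent

  near <- check_exclusion_conditions(colitis, 10, as.Date("2007-05-20"))
  expect_true(near$excluded)

  none <- check_exclusion_conditions(empty_events(), 40, as.Date("2010-05-01"))
  expect_false(none$excluded)
})

test_that("build_cohort logs planted violations and conserves counts", {
  sim <- simulate_cohort(simulation_config(n_patients = 10, seed = 11,
                                           ineligible = c(age = 0.15,
                                                          no_asthma = 0.1,
                                                          baseline = 0.1,
                                                          excl_adult = 0.1,
                                                          excl_minor = 0.05)))
  res <- build_cohort(sim$patients, sim$prescriptions, sim$events)
  expect_equal(nrow(res$cohort), 10)
  expect_equal(sum(res$cohort$eligible) + sum(res$attrition$n_removed), 10)
  truth <- sim$truth_patients
  m <- merge(res$cohort, truth, by = "patient_id", suffixes = c("", ".t"))
  expect_equal(m$eligible, m$eligible.t)
  expect_equal(m$exclusion_reason, m$exclusion_reason.t)
})

test_that("empty and all-eligible inputs give empty and all-zero logs", {
  empty <- build_cohort(one_patient()[0], ocs_scripts("2010-01-01")[0],
                        empty_events())
  expect_equal(nrow(empty$cohort), 0)
  expect_equal(sum(empty$attrition$n_removed), 0)

  idx <- as.Date("2010-05-01")
  res <- build_cohort(one_patient(), ocs_scripts(idx),
                      asthma_event("2010-05-11"))
  expect_true(all(res$cohort$eligible))
  expect_true(all(res$attrition$n_removed == 0))
})

test_that("duplicate patient ids are rejected", {
  pats <- rbind(one_patient(), one_patient())
  expect_error(build_cohort(pats, ocs_scripts("2010-01-01"), empty_events()),
               "duplicate")
})

test_that("eligibility is invariant to input row order", {
  sim <- simulate_cohort(simulation_config(n_patients = 40, seed = 3))
  res1 <- build_cohort(sim$patients, sim$prescriptions, sim$events)
  set.seed(99)
  res2 <- build_cohort(sim$patients[sample(.N)],
                       sim$prescriptions[sample(.N)],
                       sim$events[sample(.N)])
  m <- merge(res1$cohort, res2$cohort, by = "patient_id")
  expect_equal(m$eligible.x, m$eligible.y)
  expect_equal(m$exclusion_reason.x, m$exclusion_reason.y)
})

test_that("removing an exclusion diagnosis never revokes eligibility", {
  sim <- simulate_cohort(simulation_config(n_patients = 60, seed = 5,
                                           ineligible = c(age = 0, no_asthma = 0,
                                                          baseline = 0,
                                                          excl_adult = 0.2,
                                                          excl_minor = 0.1)))
  before <- build_cohort(sim$patients, sim$prescriptions, sim$events)$cohort
  stripped <- sim$events[!startsWith(category, "exclusion_condition:")]
  after <- build_cohort(sim$patients, sim$prescriptions, stripped)$cohort
  m <- merge(before, after, by = "patient_id")
  expect_true(all(!m$eligible.x | m$eligible.y))
  expect_gt(sum(m$eligible.y), sum(m$eligible.x))
})

test_that("non-OCS arm gets the registration-based reference date", {
  pat <- one_patient()
  rx <- ocs_scripts("2010-01-01")[, therapy_class := "SABA"]
  ev <- asthma_event("2006-01-10")
  res <- build_cohort(pat, rx, ev)
  expect_equal(res$cohort$arm, "non_ocs")
  expect_equal(res$cohort$index_date,
               pat$registration_start + 365)
})
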