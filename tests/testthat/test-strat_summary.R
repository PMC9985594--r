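baseline_rx <- function(drugs, classes) {
  data.table(patient_id = "P1", date = as.Date("2010-01-01"),
             drug = drugs, strength_mg_per_unit = NA_real_,
             quantity_units = 1, instruction_text = "",
             therapy_class = classes)
}

test_that("GINA step assignment follows the highest-matching rule", {
  expect_equal(assign_gina_step(baseline_rx(character(0), character(0))), "none")
  expect_equal(assign_gina_step(baseline_rx("salbutamol", "SABA")), "1")
  expect_equal(assign_gina_step(baseline_rx("budesonide_low", "ICS")), "2")
  expect_equal(assign_gina_step(
    baseline_rx(c("budesonide_low", "montelukast"), c("ICS", "LTRA"))), "3")
  expect_equal(assign_gina_step(
    baseline_rx("budesonide_formoterol_low", "ICS_LABA")), "3")
  expect_equal(assign_gina_step(
    baseline_rx("budesonide_formoterol_medium", "ICS_LABA")), "4")
  expect_equal(assign_gina_step(
    baseline_rx(c("fluticasone_salmeterol_high", "omalizumab"),
                c("ICS_LABA", "biologic"))), "5")
  expect_equal(assign_gina_step(
    baseline_rx(c("fluticasone_salmeterol_high", "tiotropium"),
                c("ICS_LABA", "LAMA"))), "5")
})

test_that("SABA fills in the pre-index year map to bands", {
  idx <- as.Date("2010-06-01")
  rx <- baseline_rx(rep("salbutamol", 4), rep("SABA", 4))
  rx$date <- idx - c(1, 100, 365, 366)  # last one outside the window
  expect_equal(count_saba_fills(rx, idx), 3)
  expect_equal(saba_band(0), "0")
  expect_equal(saba_band(2), "1-2")
  expect_equal(saba_band(7), ">=3")
})

test_that("age bands are half-open as specified", {
  expect_equal(age_band(c(4, 11, 12, 17, 18)),
               c("child", "child", "adolescent", "adolescent", "adult"))
  expect_error(age_band(3), "minimum")
})

test_that("percent rounds half away from zero to one decimal", {
  expect_equal(percent(198422, 476167), 41.7)
  expect_equal(percent(0, 5), 0)
  expect_equal(percent(1, 3), 33.3)
  expect_equal(percent(1, 8), 12.5)
  expect_equal(percent(15, 1000), 1.5)   # 1.5 exactly, stays 1.5
  expect_equal(percent(125, 10000), 1.3) # 1.25 rounds up, not to even
  expect_error(percent(1, 0), "positive")
  expect_error(percent(5, 3), "n must lie")
  # monotone in n for fixed total
  p <- percent(0:50, 50)
  expect_true(all(diff(p) >= 0))
})

test_that("pattern summary reproduces hand-computed statistics", {
  prof <- data.table(
    patient_id = c("A", "B", "C", "D"),
    n_prescriptions = c(1, 2, 2, 3),
    n_courses = c(1, 2, 2, 3),
    categories_present = c("", "sporadic", "sporadic", "sporadic"),
    detailed_label = c("Once-only", rep("Sporadic", 3)),
    simplified_label = c("once_only", rep("less_frequent", 3)),
    mixed = FALSE)
  tab <- summarize_patterns(prof)
  once <- tab[label == "Once-only"]
  expect_equal(once$n, 1)
  expect_equal(once$mean_rx, 1)
  expect_equal(once$median_rx, 1)
  spor <- tab[label == "Sporadic"]
  # counts {2,2,3}: mean 2.33; median 2; type-6 quartiles (2, 3)
  expect_equal(spor$n, 3)
  expect_equal(spor$percent, 75)
  expect_equal(spor$mean_rx, 2.3)
  expect_equal(spor$median_rx, 2)
  expect_equal(spor$q25_rx, 2)
  expect_equal(spor$q75_rx, 3)
  total <- tab[label == "Total"]
  expect_equal(total$n, 4)
  expect_equal(total$percent, 100)
})

test_that("super-rows aggregate their constituent detail rows", {
  sim <- simulate_cohort(simulation_config(n_patients = 400, seed = 31))
  cb <- build_cohort(sim$patients, sim$prescriptions, sim$events)
  cls <- classify_cohort(cb$cohort, sim$prescriptions, sim$events)
  prof <- pattern_profiles(cls)
  tab <- summarize_patterns(prof)
  freq_details <- c("Sporadic, infrequent, moderately frequent and frequent",
                    "Sporadic, infrequent and frequent",
                    "Sporadic, moderately frequent and frequent",
                    "Sporadic and frequent",
                    "Infrequent, moderately frequent and frequent",
                    "Infrequent and frequent",
                    "Moderately frequent and frequent", "Frequent only")
  expect_equal(tab[label == "Any frequent", n],
               sum(tab[label %in% freq_details, n]))
  expect_equal(tab[level == "detail", sum(n)], tab[level == "total", n])
})

test_that("Pearson chi-square matches the closed form and test invariances", {
  fix <- matrix(c(10, 20, 20, 10), nrow = 2, byrow = TRUE)
  res <- crosstab_chisq(fix)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)

  same <- matrix(c(5, 7, 5, 7), nrow = 2, byrow = TRUE)
  expect_equal(crosstab_chisq(same)$statistic, 0)

  unif <- matrix(3, 3, 3)
  u <- suppressWarnings(crosstab_chisq(unif))
  expect_equal(u$statistic, 0)
  expect_equal(u$df, 4)

  # row permutation leaves the statistic unchanged
  m <- matrix(c(12, 5, 9, 20, 3, 8), nrow = 3)
  expect_equal(suppressWarnings(crosstab_chisq(m[c(3, 1, 2), ])$statistic),
               suppressWarnings(crosstab_chisq(m)$statistic))

  # zero-margin rows are dropped with a warning
  z <- rbind(fix, c(0, 0))
  expect_warning(rz <- crosstab_chisq(z), "zero-margin")
  expect_equal(rz$statistic, 20 / 3, tolerance = 1e-12)
})

test_that("column percents sum to ~100 within each pattern column", {
  sim <- simulate_cohort(simulation_config(n_patients = 300, seed = 9))
  cb <- build_cohort(sim$patients, sim$prescriptions, sim$events)
  cls <- classify_cohort(cb$cohort, sim$prescriptions, sim$events)
  prof <- pattern_profiles(cls)
  strata <- stratify_cohort(cb$cohort, sim$prescriptions)
  s <- suppressWarnings(stratified_summary(prof, strata))
  expect_true(all(abs(colSums(s$by_saba$col_percent) - 100) <= 0.2))
  expect_true(all(abs(colSums(s$by_age$col_percent) - 100) <= 0.2))
  expect_equal(sum(s$by_age$counts), nrow(prof))
  expect_equal(s$gina_distribution[, sum(n)], nrow(prof))
})
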