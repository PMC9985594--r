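# Baseline stratifiers (GINA 2020 step, SABA fill band, age band),
# pattern summary tables and chi-square contingency analyses.

#' Bundled ICS dose-band lookup
#'
#' Maps inhaled-controller product names to therapy class and ICS dose band
#' (low/medium/high), following GINA 2020 dose-band conventions. Editable:
#' supply an alternative CSV with the same columns.
#'
#' @param path Optional path to an alternative table.
#' @return data.table with columns `drug`, `therapy_class`, `ics_dose_band`.
#' @export
ics_dose_bands <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ics_dose_bands.csv", package = "ocspatterns")
  }
  data.table::fread(path)
}

#' Assign a GINA 2020 treatment step from baseline therapy
#'
#' Highest-matching-step rule, applied to the therapy classes dispensed in
#' the baseline window: Step 5 for biologic add-on therapy (or LAMA add-on
#' to high-dose ICS-LABA); Step 4 for medium/high-dose ICS-LABA; Step 3 for
#' low-dose ICS-LABA or ICS plus LTRA; Step 2 for ICS (or LTRA) alone;
#' Step 1 for a reliever-only strategy; `"none"` when no asthma medication
#' was dispensed.
#'
#' @param baseline_rx data.table of one patient's prescriptions inside the
#'   baseline window (columns `drug`, `therapy_class`).
#' @param bands ICS dose-band lookup, default [ics_dose_bands()].
#' @return One of `"none"`, `"1"` ... `"5"`.
#' @export
assign_gina_step <- function(baseline_rx, bands = ics_dose_bands()) {
  known <- c(asthma_therapy_classes(), "OCS", "other")
  unknown <- setdiff(unique(baseline_rx$therapy_class), known)
  if (length(unknown)) {
    warning(sprintf("ignoring %d prescription(s) with unknown therapy class",
                    sum(baseline_rx$therapy_class %in% unknown)))
  }
  cls <- unique(baseline_rx$therapy_class)
  has <- function(x) x %in% cls
  if (!any(asthma_therapy_classes() %in% cls)) return("none")
  band_rank <- c(low = 1, medium = 2, high = 3)
  iclaba_band <- 0
  if (has("ICS_LABA")) {
    drugs <- baseline_rx$drug[baseline_rx$therapy_class == "ICS_LABA"]
    b <- bands$ics_dose_band[match(drugs, bands$drug)]
    b[is.na(b)] <- "medium"  # unlisted combination product: assume mid-band
    iclaba_band <- max(band_rank[b])
  }
  if (has("biologic")) return("5")
  if (iclaba_band == 3 && has("LAMA")) return("5")
  if (iclaba_band >= 2) return("4")
  if (iclaba_band == 1) return("3")
  if (has("ICS") && has("LTRA")) return("3")
  if (has("ICS")) return("2")
  if (has("LTRA")) return("2")
  "1"
}

#' Count SABA fills in the baseline window and band them
#'
#' @param prescriptions One patient's prescriptions.
#' @param index_date Index date; the window is the 365 days before it,
#'   index day excluded.
#' @return Integer fill count.
#' @export
count_saba_fills <- function(prescriptions, index_date) {
  sum(prescriptions$therapy_class == "SABA" &
        prescriptions$date >= index_date - 365L &
        prescriptions$date <= index_date - 1L)
}

#' @rdname count_saba_fills
#' @param n_fills Integer count of SABA fills.
#' @return `saba_band()`: one of `"0"`, `"1-2"`, `">=3"`.
#' @export
saba_band <- function(n_fills) {
  ifelse(n_fills == 0, "0", ifelse(n_fills <= 2, "1-2", ">=3"))
}

#' Age band at index
#'
#' @param age Completed years at index (must be >= 4; younger patients are
#'   excluded upstream).
#' @return `"child"` (4 to <12), `"adolescent"` (12 to <18), `"adult"`
#'   (>= 18).
#' @export
age_band <- function(age) {
  if (any(age < 4)) stop("age below cohort minimum of 4", call. = FALSE)
  ifelse(age < 12, "child", ifelse(age < 18, "adolescent", "adult"))
}

#' Baseline stratifiers for all eligible OCS-arm patients
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param prescriptions Normalized prescriptions table.
#' @param bands ICS dose-band lookup.
#' @return data.table: `patient_id`, `gina_step`, `saba_band`, `age_band`.
#' @export
stratify_cohort <- function(cohort, prescriptions, bands = ics_dose_bands()) {
  elig <- cohort[cohort$eligible & cohort$arm == "ocs"]
  rx_split <- split(prescriptions[prescriptions$patient_id %in% elig$patient_id],
                    by = "patient_id")
  empty_rx <- prescriptions[0]
  res <- lapply(seq_len(nrow(elig)), function(i) {
    rx <- rx_split[[elig$patient_id[i]]]
    if (is.null(rx)) rx <- empty_rx
    idx <- elig$index_date[i]
    baseline <- rx[rx$date >= idx - 365L & rx$date <= idx - 1L]
    data.table::data.table(
      patient_id = elig$patient_id[i],
      gina_step = assign_gina_step(baseline, bands),
      saba_band = saba_band(count_saba_fills(rx, idx)),
      age_band = age_band(elig$age_at_index[i]))
  })
  data.table::rbindlist(res)
}

# Half-away-from-zero rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' One-decimal percentage, half rounded away from zero
#'
#' @param n Numerator count(s), `0 <= n <= total`.
#' @param total Positive total.
#' @return `100 * n / total` rounded half away from zero to 1 decimal.
#' @export
#' @examples
#' percent(198422, 476167)  # 41.7
percent <- function(n, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(n < 0 | n > total)) stop("n must lie in [0, total]", call. = FALSE)
  round_half_up(100 * n / total, 1)
}

# Quantiles by linear interpolation at (n+1)p (type 6), the convention
# documented for all IQR output of this package.
pkg_quantile <- function(x, p) unname(stats::quantile(x, p, type = 6))

#' Pattern summary table with super-rows
#'
#' Builds the detailed pattern breakdown: one row per detailed label, a
#' super-row per most-severe category ("Any infrequent", "Any moderately
#' frequent", "Any frequent") aggregating its constituent rows, and a Total
#' row. Per row: n, percent of total, mean (SD) and median (IQR, 25th–75th
#' percentile, type-6 quantiles) of the per-patient prescription counts.
#'
#' @param profiles Profiles from [pattern_profiles()] (needs columns
#'   `detailed_label`, `categories_present`, `n_prescriptions`).
#' @return data.table: `label`, `level` (`"detail"`, `"super"`, `"total"`),
#'   `n`, `percent`, `mean_rx`, `sd_rx`, `median_rx`, `q25_rx`, `q75_rx`.
#' @export
summarize_patterns <- function(profiles) {
  total_n <- nrow(profiles)
  if (!total_n) stop("no profiles to summarize", call. = FALSE)
  lv <- gap_category_levels()
  most_severe_of <- function(cats) {
    if (!nzchar(cats)) return("once_only")
    lv[max(match(strsplit(cats, ",")[[1]], lv))]
  }
  prof <- data.table::copy(profiles)
  prof[, most_severe := vapply(categories_present, most_severe_of, character(1))]

  stat_row <- function(label, level, counts) {
    data.table::data.table(
      label = label, level = level, n = length(counts),
      percent = percent(length(counts), total_n),
      mean_rx = round_half_up(mean(counts), 1),
      sd_rx = round_half_up(stats::sd(counts), 1),
      median_rx = round_half_up(pkg_quantile(counts, .5), 1),
      q25_rx = round_half_up(pkg_quantile(counts, .25), 1),
      q75_rx = round_half_up(pkg_quantile(counts, .75), 1))
  }
  super_for <- list(infrequent = "Any infrequent",
                    moderately_frequent = "Any moderately frequent",
                    frequent = "Any frequent")
  rows <- list()
  for (lab in all_detailed_labels()) {
    sub <- prof[prof$detailed_label == lab]
    sev <- if (lab == "Once-only") "once_only" else
      lv[max(match(strsplit(tolower(gsub(" only$", "", lab)), ", | and ")[[1]],
                   gsub("_", " ", lv)), na.rm = TRUE)]
    # emit the super-row when entering a new super-group
    if (sev %in% names(super_for) && !is.null(super_for[[sev]])) {
      grp <- prof[prof$most_severe == sev]
      if (nrow(grp)) rows <- c(rows, list(stat_row(super_for[[sev]], "super",
                                                   grp$n_prescriptions)))
      super_for[[sev]] <- NULL
    }
    if (nrow(sub)) rows <- c(rows, list(stat_row(lab, "detail",
                                                 sub$n_prescriptions)))
  }
  rows <- c(rows, list(stat_row("Total", "total", prof$n_prescriptions)))
  data.table::rbindlist(rows)
}

#' Contingency table, column percentages and Pearson chi-square
#'
#' Cross-tabulates two categorical vectors, drops zero-margin rows/columns
#' with a warning, and applies Pearson's chi-square test without continuity
#' correction (`df = (r-1)(c-1)`). Column percentages follow the published
#' table layout (each column sums to 100).
#'
#' @param rows,cols Equal-length categorical vectors (rows: stratifier,
#'   cols: pattern label), or `rows` may be a pre-built contingency matrix
#'   with `cols` missing.
#' @return List: `counts` (matrix), `col_percent` (matrix, 1 decimal),
#'   `statistic`, `df`, `p_value`.
#' @export
crosstab_chisq <- function(rows, cols = NULL) {
  tab <- if (is.matrix(rows)) rows else unclass(table(rows, cols))
  zero_r <- rowSums(tab) == 0
  zero_c <- colSums(tab) == 0
  if (any(zero_r) || any(zero_c)) {
    warning("dropping zero-margin rows/columns from contingency table")
    tab <- tab[!zero_r, !zero_c, drop = FALSE]
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  pct <- apply(tab, 2, function(col) percent(col, sum(col)))
  dimnames(pct) <- dimnames(tab)
  list(counts = tab, col_percent = pct,
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Simplified pattern by stratifier tables
#'
#' Produces the published-table-shaped summaries: simplified pattern
#' (columns) by SABA band and by age band (rows), each with counts, column
#' percentages and a chi-square test, plus the GINA-step distribution of
#' the cohort with the share of frequent-pattern patients per step.
#'
#' @param profiles From [pattern_profiles()].
#' @param strata From [stratify_cohort()].
#' @return List of three elements `by_saba`, `by_age` (each as
#'   [crosstab_chisq()] output) and `gina_distribution` (data.table with
#'   `gina_step`, `n`, `percent`, `pct_frequent`).
#' @export
stratified_summary <- function(profiles, strata) {
  m <- merge(profiles[, .(patient_id, simplified_label)], strata,
             by = "patient_id")
  pat_levels <- c("once_only", "less_frequent", "frequent")
  pat <- factor(m$simplified_label, levels = pat_levels)
  by_saba <- crosstab_chisq(factor(m$saba_band, levels = c("0", "1-2", ">=3")),
                            pat)
  by_age <- crosstab_chisq(factor(m$age_band,
                                  levels = c("child", "adolescent", "adult")),
                           pat)
  gina <- m[, .(n = .N, pct_frequent = percent(sum(simplified_label == "frequent"), .N)),
            by = .(gina_step)]
  data.table::setorder(gina, gina_step)
  gina[, percent := percent(n, sum(n))]
  list(by_saba = by_saba, by_age = by_age,
       gina_distribution = gina[, .(gina_step, n, percent, pct_frequent)])
}

#' Dose-per-prescription histogram counts
#'
#' @param classified_scripts Scripts table from [classify_cohort()].
#' @param breaks Histogram bin edges in prednisolone-equivalent mg/day.
#' @return data.table with `bin` and `n` (unknown doses counted separately).
#' @export
dose_histogram <- function(classified_scripts,
                           breaks = c(0, 5, 10, 20, 30, 40, 50, 75, 100, Inf)) {
  d <- classified_scripts$pred_equiv_mg_per_day
  known <- d[!is.na(d)]
  cuts <- cut(known, breaks = breaks, right = FALSE)
  out <- data.table::data.table(bin = c(levels(cuts), "unknown"),
                                n = c(as.integer(table(cuts)), sum(is.na(d))))
  out
}
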