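# Gap sequencing: inter-course gaps of intermittent-only patients mapped to
# frequency categories, a detailed combination taxonomy and a simplified
# three-way label.

# Severity order used for naming and super-rows: longest typical gap first.
gap_category_levels <- function() {
  c("sporadic", "infrequent", "moderately_frequent", "frequent")
}

gap_category_display <- c(
  sporadic = "Sporadic", infrequent = "Infrequent",
  moderately_frequent = "Moderately frequent", frequent = "Frequent")

#' Gap category definitions
#'
#' @return data.table with one row per category: `category`, `min_days`,
#'   `max_days` (`Inf` for sporadic). The four categories partition the
#'   positive integers: frequent `< 90`, moderately frequent `90–181`,
#'   infrequent `182–364`, sporadic `>= 365`.
#' @export
gap_categories <- function() {
  data.table::data.table(
    category = gap_category_levels(),
    min_days = c(365, 182, 90, 1),
    max_days = c(Inf, 364, 181, 89))
}

#' Collapse script dates to ordered distinct course dates
#'
#' One script is one course; same-day scripts merge into one course. No
#' course-duration arithmetic is applied.
#'
#' @param dates Dates of the intermittent-labelled scripts of one patient.
#' @return Sorted unique dates.
#' @export
collapse_courses <- function(dates) {
  if (!length(dates)) {
    stop("no course dates; pattern sequencing requires >= 1 intermittent script",
         call. = FALSE)
  }
  sort(unique(dates))
}

#' Categorize an inter-course gap
#'
#' @param days Positive integer vector of gaps in days.
#' @return Character vector: `"frequent"` (< 90), `"moderately_frequent"`
#'   (90–181), `"infrequent"` (182–364), `"sporadic"` (>= 365).
#' @export
#' @examples
#' categorize_gap(c(89, 90, 181, 182, 364, 365))
categorize_gap <- function(days) {
  if (any(is.na(days)) || any(days < 1)) {
    stop("gaps must be positive integers (days >= 1)", call. = FALSE)
  }
  ifelse(days < 90, "frequent",
         ifelse(days <= 181, "moderately_frequent",
                ifelse(days <= 364, "infrequent", "sporadic")))
}

#' Canonical detailed pattern label for a set of gap categories
#'
#' Naming mirrors the published taxonomy: `"Once-only"` for patients with a
#' single course; `"Sporadic"` for sporadic-only; `"<Category> only"` for the
#' other singletons; combinations listed longest-gap-first and joined with
#' commas and a final "and" (e.g. `"Sporadic, infrequent and frequent"`).
#'
#' @param categories Character vector (subset of
#'   `gap_categories()$category`); empty means once-only.
#' @return A single label string.
#' @export
detailed_label <- function(categories) {
  categories <- unique(categories)
  stopifnot(all(categories %in% gap_category_levels()))
  if (!length(categories)) return("Once-only")
  ordered <- gap_category_levels()[gap_category_levels() %in% categories]
  if (length(ordered) == 1) {
    if (ordered == "sporadic") return("Sporadic")
    return(paste(gap_category_display[[ordered]], "only"))
  }
  words <- tolower(gap_category_display[ordered])
  words[1] <- gap_category_display[[ordered[1]]]
  if (length(words) == 2) return(paste(words, collapse = " and "))
  paste0(paste(words[-length(words)], collapse = ", "), " and ",
         words[length(words)])
}

#' All detailed pattern labels, in canonical table order
#'
#' Enumerates once-only plus every non-empty subset of the four gap
#' categories (16 labels), ordered as in the published breakdown: once-only,
#' sporadic-only, then super-groups by the most severe (shortest-gap)
#' category present.
#'
#' @return Character vector of 16 labels.
#' @export
all_detailed_labels <- function() {
  lv <- gap_category_levels()
  subsets <- lapply(seq_len(2^4 - 1), function(m) lv[bitwAnd(m, 2^(0:3)) > 0])
  labels <- vapply(subsets, detailed_label, character(1))
  sev <- vapply(subsets, function(s) max(match(s, lv)), integer(1))
  size <- lengths(subsets)
  out <- c("Once-only", "Sporadic")
  for (s in 2:4) {
    idx <- which(sev == s)
    only <- idx[size[idx] == 1]
    combos <- idx[size[idx] > 1]
    # combinations ordered lexicographically by their severity indices so
    # longer-gap categories lead (e.g. all sporadic-containing rows first)
    key <- vapply(subsets[combos], function(x)
      paste(sprintf("%02d", sort(match(x, lv))), collapse = ""), character(1))
    combos <- combos[order(key)]
    # "Frequent only" closes its group in the published layout; the other
    # singleton rows open theirs
    out <- c(out, if (s < 4) labels[only], labels[combos],
             if (s == 4) labels[only])
  }
  out
}

#' Simplified three-way pattern label
#'
#' @param n_courses Number of distinct course dates.
#' @param categories Gap categories present.
#' @return `"once_only"` when there is a single course; `"frequent"` when
#'   any gap is `< 90` days; `"less_frequent"` otherwise.
#' @export
simplify_label <- function(n_courses, categories) {
  if (n_courses == 1) return("once_only")
  if ("frequent" %in% categories) return("frequent")
  "less_frequent"
}

#' Derive the gap-pattern profile for one patient
#'
#' @param dates Dates of the patient's intermittent scripts (collapsed to
#'   courses internally).
#' @return One-row data.table: `n_courses`, `categories_present`
#'   (comma-separated, severity order), `detailed_label`,
#'   `simplified_label`, `mixed`.
#' @export
derive_profile <- function(dates) {
  courses <- collapse_courses(dates)
  gaps <- as.integer(diff(courses))
  cats <- if (length(gaps)) unique(categorize_gap(gaps)) else character(0)
  cats <- gap_category_levels()[gap_category_levels() %in% cats]
  data.table::data.table(
    n_courses = length(courses),
    categories_present = paste(cats, collapse = ","),
    detailed_label = detailed_label(cats),
    simplified_label = simplify_label(length(courses), cats),
    mixed = length(cats) > 1)
}

#' Gap-pattern profiles for all intermittent-only patients
#'
#' @param classified Output of [classify_cohort()]: per-script labels and
#'   per-patient use. Only patients with `patient_use == "intermittent_only"`
#'   receive a profile.
#' @return data.table: `patient_id`, `n_prescriptions` (count of
#'   intermittent scripts), `n_courses`, `categories_present`,
#'   `detailed_label`, `simplified_label`, `mixed`.
#' @export
pattern_profiles <- function(classified) {
  ids <- classified$patients$patient_id[
    classified$patients$patient_use == "intermittent_only"]
  sc <- classified$scripts[classified$scripts$patient_id %in% ids &
                             classified$scripts$label == "intermittent"]
  prof <- sc[, {
    p <- derive_profile(date)
    cbind(data.table::data.table(n_prescriptions = .N), p)
  }, by = patient_id]
  prof[]
}
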