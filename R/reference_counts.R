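#' Published pattern counts for a large UK asthma cohort
#'
#' Detailed intermittent-OCS pattern counts reported for a UK primary-care
#' asthma cohort of 476,167 patients with intermittent-only OCS use. Used as
#' the default pattern mixture of the synthetic generator and as input to
#' aggregation identities (super-row sums, single-vs-mixed split, simplified
#' collapse, percentage cells).
#'
#' @return data.table with columns `label` (the 16 detailed pattern labels,
#'   canonical order) and `n`.
#' @export
reference_pattern_counts <- function() {
  data.table::data.table(
    label = all_detailed_labels(),
    n = c(
      198422L,  # Once-only
      65632L,   # Sporadic
      1445L,    # Infrequent only
      32409L,   # Sporadic and infrequent
      155L,     # Moderately frequent only
      8836L,    # Sporadic, infrequent and moderately frequent
      17371L,   # Sporadic and moderately frequent
      1571L,    # Infrequent and moderately frequent
      39842L,   # Sporadic, infrequent, moderately frequent and frequent
      29432L,   # Sporadic, infrequent and frequent
      17455L,   # Sporadic, moderately frequent and frequent
      56661L,   # Sporadic and frequent
      3083L,    # Infrequent, moderately frequent and frequent
      2136L,    # Infrequent and frequent
      809L,     # Moderately frequent and frequent
      908L))    # Frequent only
}

#' Aggregate detailed pattern counts into super-rows and splits
#'
#' Given per-detailed-label patient counts, computes the derived rows of the
#' pattern breakdown: the "Any infrequent/moderately frequent/frequent"
#' super-rows (grouping by the most severe category present), the
#' single-category versus mixed-pattern split, the simplified three-way
#' collapse and the total.
#'
#' @param counts data.table with columns `label`, `n` covering the 16
#'   detailed labels (e.g. [reference_pattern_counts()]).
#' @return Named list of integers: `any_infrequent`, `any_moderately_frequent`,
#'   `any_frequent`, `single_category`, `mixed`, `once_only`,
#'   `less_frequent`, `frequent`, `total`.
#' @export
aggregate_pattern_counts <- function(counts) {
  stopifnot(setequal(counts$label, all_detailed_labels()))
  lv <- gap_category_levels()
  info <- lapply(counts$label, function(lab) {
    if (lab == "Once-only") return(list(sev = 0L, size = 0L))
    parts <- strsplit(tolower(gsub(" only$", "", lab)), ", | and ")[[1]]
    idx <- match(parts, gsub("_", " ", lv))
    list(sev = max(idx), size = length(idx))
  })
  sev <- vapply(info, `[[`, integer(1), "sev")
  size <- vapply(info, `[[`, integer(1), "size")
  n <- counts$n
  list(
    any_infrequent = sum(n[sev == 2]),
    any_moderately_frequent = sum(n[sev == 3]),
    any_frequent = sum(n[sev == 4]),
    single_category = sum(n[size <= 1]),
    mixed = sum(n[size > 1]),
    once_only = sum(n[sev == 0]),
    less_frequent = sum(n[sev %in% 1:3]),
    frequent = sum(n[sev == 4]),
    total = sum(n))
}
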