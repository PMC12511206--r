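# Weight stratification, median/IQR summaries, percentage differences,
# Mann-Whitney comparison and the per-quantity cohort comparison table.

#' Standard weight categories for the audit
#'
#' Seven contiguous half-open bins: `<50` = (0, 50), then 10-kg bins up to
#' `90-99` = \[90, 100), and `>100` = \[100, Inf). A patient of exactly
#' 100 kg falls in the `>100` bin; that keeps the bins contiguous where the
#' category names alone leave 100 kg unassigned.
#'
#' @return Tibble with columns `label`, `lower` (inclusive), `upper`
#'   (exclusive).
#' @export
weight_category_scheme <- function() {
  tibble::tibble(
    label = c("<50", "50–59", "60–69", "70–79",
              "80–89", "90–99", ">100"),
    lower = c(0, 50, 60, 70, 80, 90, 100),
    upper = c(50, 60, 70, 80, 90, 100, Inf))
}

#' Assign a weight category
#'
#' @param weight kg, strictly positive; vectorised.
#' @param scheme A [weight_category_scheme()]-style tibble.
#' @return Character vector of category labels.
#' @examples
#' assign_weight_category(c(46, 99.9, 100))
#' @export
assign_weight_category <- function(weight, scheme = weight_category_scheme()) {
  stopifnot_number(weight, "weight", positive = TRUE)
  idx <- findInterval(weight, scheme$lower)
  scheme$label[idx]
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between the closest order statistics
#' (type-7 quantiles, the common scientific-software default). IQRs differ
#' slightly across quantile conventions, so the choice is fixed here.
#'
#' @param values Non-empty numeric vector; `NA`s are an error (strip them
#'   first — absence is meaningful and reported as reduced n upstream).
#' @return Named list `median`, `q1`, `q3`.
#' @examples
#' median_iqr(c(1, 2, 3, 4))  # 2.5 (1.75-3.25)
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) abort_empty("cannot summarise an empty vector")
  stopifnot_number(values, "values")
  q <- unname(quantile(values, c(0.5, 0.25, 0.75), type = 7))
  list(median = q[1], q1 = q[2], q3 = q[3])
}

#' Percentage difference relative to a reference cohort
#'
#' `100 x (comparison - reference) / reference`. The reference is always
#' the earlier (conventional-scanner) cohort, so a negative value is a dose
#' or activity reduction after the transition.
#'
#' @param reference Non-zero reference value.
#' @param comparison Comparison value.
#' @return Percent, full precision.
#' @examples
#' round(percent_difference(303, 149.5), 1)  # -50.7
#' @export
percent_difference <- function(reference, comparison) {
  stopifnot_number(reference, "reference")
  stopifnot_number(comparison, "comparison")
  if (any(reference == 0)) abort_invalid("`reference` must be non-zero")
  100 * (comparison - reference) / reference
}

#' Two-sample Mann-Whitney U test
#'
#' Two-sided test of location shift. The U statistic counts pairs where the
#' first sample exceeds the second, with half-credit for ties (midranks).
#' The p-value is exact (full enumeration of the null permutation
#' distribution) when the combined sample size is at most `exact_limit` and
#' there are no ties; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction is used. Samples with
#' zero rank variance (all values identical) return p = 1.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param exact_limit Combined-size threshold for the exact null
#'   distribution; 12 keeps the enumeration instant and deterministic.
#' @return List with `U` (for `sample_a`) and `p_value`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_limit = 12) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort_empty("both samples must be non-empty")
  }
  stopifnot_number(sample_a, "sample_a")
  stopifnot_number(sample_b, "sample_b")
  pooled <- c(sample_a, sample_b)
  ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1) {
    return(list(U = length(sample_a) * length(sample_b) / 2, p_value = 1))
  }
  use_exact <- !ties && length(pooled) <= exact_limit
  ht <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = use_exact, correct = TRUE))
  list(U = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' CT share of the total effective dose
#'
#' `100 x ED_CT / ED_total`, per patient; stratified medians of the
#' per-patient proportions summarise a cohort. Invariant under a common
#' rescaling of both doses.
#'
#' @param ed_ct CT effective dose in mSv, at most `ed_total`.
#' @param ed_total Total effective dose in mSv, strictly positive.
#' @return Percent.
#' @export
ct_dose_proportion <- function(ed_ct, ed_total) {
  stopifnot_number(ed_ct, "ed_ct", nonneg = TRUE)
  stopifnot_number(ed_total, "ed_total", positive = TRUE)
  if (any(ed_ct > ed_total * (1 + 1e-12))) {
    abort_invalid("`ed_ct` cannot exceed `ed_total`")
  }
  100 * ed_ct / ed_total
}

# Quantities compared between cohorts, in reporting order.
comparison_quantities <- function() {
  c("weight", "injected_activity", "ed_ct", "ed_pet", "ed_pet_ws",
    "ed_pet_bv", "ed_total_icrp", "ed_total_ws", "ed_total_bv")
}

#' Stratified cohort comparison
#'
#' Builds the audit's central table: for each quantity (weight, injected
#' activity, CT dose, the three PET dose variants and the three totals) and
#' each stratum (`ALL` plus every weight category), the per-cohort median
#' and IQR, sample sizes, percentage difference of medians (reference =
#' first cohort) and a two-sided Mann-Whitney p-value with a significance
#' flag at alpha = 0.05. Blood-volume quantities use only patients with a
#' recorded height, so their n is reduced accordingly.
#'
#' @param records_a,records_b Patient tables satisfying
#'   [validate_patient_records()]; `records_a` is the reference cohort.
#' @param scheme A [dose_scheme()].
#' @param categories A [weight_category_scheme()]-style tibble.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with one row per quantity x stratum: `quantity`,
#'   `stratum`, `n_a`, `median_a`, `q1_a`, `q3_a`, `n_b`, `median_b`,
#'   `q1_b`, `q3_b`, `percent_difference`, `p_value`, `significant`.
#' @export
compare_cohorts <- function(records_a, records_b,
                            scheme = default_dose_scheme(),
                            categories = weight_category_scheme(),
                            alpha = 0.05) {
  da <- compute_doses(records_a, scheme)
  db <- compute_doses(records_b, scheme)
  da$.category <- assign_weight_category(da$weight, categories)
  db$.category <- assign_weight_category(db$weight, categories)
  strata <- c("ALL", categories$label)

  one_row <- function(qty, stratum) {
    va <- if (stratum == "ALL") da[[qty]] else da[[qty]][da$.category == stratum]
    vb <- if (stratum == "ALL") db[[qty]] else db[[qty]][db$.category == stratum]
    va <- va[!is.na(va)]
    vb <- vb[!is.na(vb)]
    sa <- if (length(va)) median_iqr(va) else list(median = NA_real_,
                                                   q1 = NA_real_, q3 = NA_real_)
    sb <- if (length(vb)) median_iqr(vb) else list(median = NA_real_,
                                                   q1 = NA_real_, q3 = NA_real_)
    pd <- if (!is.na(sa$median) && !is.na(sb$median) && sa$median != 0) {
      percent_difference(sa$median, sb$median)
    } else NA_real_
    pv <- if (length(va) && length(vb)) {
      mann_whitney_u(va, vb)$p_value
    } else NA_real_
    tibble::tibble(
      quantity = qty, stratum = stratum,
      n_a = length(va), median_a = sa$median, q1_a = sa$q1, q3_a = sa$q3,
      n_b = length(vb), median_b = sb$median, q1_b = sb$q1, q3_b = sb$q3,
      percent_difference = pd, p_value = pv,
      significant = !is.na(pv) & pv < alpha)
  }

  grid <- expand.grid(quantity = comparison_quantities(), stratum = strata,
                      stringsAsFactors = FALSE)
  dplyr::bind_rows(Map(one_row, grid$quantity, grid$stratum))
}

#' Stratified CT dose proportion table
#'
#' Per-patient CT share of the weight-scaled total dose
#' ([ct_dose_proportion()]), summarised by median per stratum and cohort.
#'
#' @inheritParams compare_cohorts
#' @return Tibble with columns `stratum`, `n_a`, `proportion_a`, `n_b`,
#'   `proportion_b` (medians, percent).
#' @export
ct_proportion_table <- function(records_a, records_b,
                                scheme = default_dose_scheme(),
                                categories = weight_category_scheme()) {
  da <- compute_doses(records_a, scheme)
  db <- compute_doses(records_b, scheme)
  da$.prop <- ct_dose_proportion(da$ed_ct, da$ed_total_ws)
  db$.prop <- ct_dose_proportion(db$ed_ct, db$ed_total_ws)
  da$.category <- assign_weight_category(da$weight, categories)
  db$.category <- assign_weight_category(db$weight, categories)
  strata <- c("ALL", categories$label)
  rows <- lapply(strata, function(s) {
    pa <- if (s == "ALL") da$.prop else da$.prop[da$.category == s]
    pb <- if (s == "ALL") db$.prop else db$.prop[db$.category == s]
    tibble::tibble(
      stratum = s,
      n_a = length(pa),
      proportion_a = if (length(pa)) median(pa) else NA_real_,
      n_b = length(pb),
      proportion_b = if (length(pb)) median(pb) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
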