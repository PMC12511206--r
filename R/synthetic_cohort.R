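# Seeded synthetic patient cohorts with the statistical structure of the
# audited hospital data: stratified weights, protocol-driven injected
# activity with multiplicative jitter, a log-linear DLP model, BMI-derived
# heights with realistic missingness, and cohort gender ratios.

#' Specification of a synthetic patient cohort
#'
#' A cohort spec fixes everything the generator needs: per-stratum sample
#' sizes and target median weights, the injected-activity protocol and its
#' jitter, the log-linear DLP model, the BMI model from which heights are
#' back-computed, the height missingness rate, the gender ratio and a seed.
#' [mct_cohort_spec()] and [quadra_cohort_spec()] carry the defaults that
#' emulate the two audited cohorts: 484 conventional-scanner studies with a
#' 250 MBq protocol (300 MBq above 90 kg) and median activity near 303 MBq,
#' and 553 LAFOV studies on a fixed 150 MBq protocol with median near
#' 149.5 MBq; heights recorded for 387 and 134 patients respectively.
#'
#' @param cohort_name Cohort label carried into every record.
#' @param strata Tibble with columns `label`, `n`, `target_median` (kg),
#'   `spread` (kg, truncated-normal SD), `lower`, `upper` (truncation
#'   bounds in kg). Open-ended bins are truncated at 35 and 160 kg.
#' @param activity_protocol List: `rule` (`"weight_tiered"` or `"fixed"`),
#'   `standard` (MBq), and for the tiered rule `heavy` (MBq) and
#'   `heavy_threshold` (kg); plus `jitter_median` (multiplicative) and
#'   `jitter_sdlog` (lognormal SD).
#' @param dlp_model List `intercept`, `slope`, `sdlog` of
#'   `DLP = exp(intercept + slope x weight + N(0, sdlog))` in mGy·cm.
#' @param height_model List `mean_bmi`, `sd_bmi`, `min_bmi`, `max_bmi`
#'   (kg/m2); height in cm is back-computed from weight and a truncated
#'   normal BMI draw.
#' @param height_missing_rate Fraction of patients without a recorded
#'   height; exactly `round(n x (1 - rate))` patients get a height.
#' @param gender_ratio_male Fraction male among patients of known gender.
#' @param gender_unknown Count of patients with unknown gender.
#' @param seed Integer RNG seed; the generator is byte-reproducible for a
#'   fixed spec + seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_name, strata, activity_protocol, dlp_model,
                        height_model, height_missing_rate,
                        gender_ratio_male, gender_unknown = 0, seed = 1L) {
  strata <- tibble::as_tibble(strata)
  needed <- c("label", "n", "target_median", "spread", "lower", "upper")
  if (length(setdiff(needed, names(strata)))) {
    abort_config("`strata` must have columns label, n, target_median, spread, lower, upper")
  }
  if (any(strata$n < 0)) abort_config("stratum sizes must be non-negative")
  if (any(strata$spread < 0)) abort_config("weight spreads must be non-negative")
  if (any(strata$upper <= strata$lower)) {
    abort_config("stratum upper bounds must exceed lower bounds")
  }
  if (height_missing_rate < 0 || height_missing_rate > 1) {
    abort_config("`height_missing_rate` must lie in [0, 1]")
  }
  if (gender_ratio_male < 0 || gender_ratio_male > 1) {
    abort_config("`gender_ratio_male` must lie in [0, 1]")
  }
  if (is.null(activity_protocol$rule) ||
      !activity_protocol$rule %in% c("weight_tiered", "fixed")) {
    abort_config("unknown activity protocol rule")
  }
  if (!is.null(activity_protocol$jitter_sdlog) &&
      activity_protocol$jitter_sdlog < 0) {
    abort_config("jitter sd must be non-negative")
  }
  if (dlp_model$sdlog < 0) abort_config("DLP noise sd must be non-negative")
  structure(list(cohort_name = cohort_name, strata = strata,
                 activity_protocol = activity_protocol,
                 dlp_model = dlp_model, height_model = height_model,
                 height_missing_rate = height_missing_rate,
                 gender_ratio_male = gender_ratio_male,
                 gender_unknown = gender_unknown,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: %d patients in %d strata, seed %d\n",
              x$cohort_name, sum(x$strata$n), nrow(x$strata), x$seed))
  invisible(x)
}

# Stratum scaffolding shared by the two default specs. Weight-category
# bounds follow weight_category_scheme(); open-ended bins truncated to
# plausible clinical extremes (35 and 160 kg).
audit_strata <- function(n, target_median, spread) {
  cats <- weight_category_scheme()
  tibble::tibble(label = cats$label, n = n, target_median = target_median,
                 spread = spread,
                 lower = replace(cats$lower, 1, 35),
                 upper = replace(cats$upper, nrow(cats), 160))
}

#' @rdname cohort_spec
#' @export
mct_cohort_spec <- function(seed = 20260101L) {
  cohort_spec(
    cohort_name = "mCT",
    strata = audit_strata(
      n = c(16, 75, 110, 107, 78, 63, 35),
      target_median = c(45.9, 56, 65, 74, 83.5, 93, 108),
      spread = c(3.5, 3, 3, 3, 3, 3, 8)),
    activity_protocol = list(rule = "weight_tiered", standard = 250,
                             heavy = 300, heavy_threshold = 90,
                             jitter_median = 1.17, jitter_sdlog = 0.15),
    dlp_model = list(intercept = 4.7970, slope = 0.016506, sdlog = 0.22),
    height_model = list(mean_bmi = 26, sd_bmi = 4, min_bmi = 15, max_bmi = 45),
    height_missing_rate = 97 / 484,
    gender_ratio_male = 273 / 483,
    gender_unknown = 1,
    seed = seed)
}

#' @rdname cohort_spec
#' @export
quadra_cohort_spec <- function(seed = 20260102L) {
  cohort_spec(
    cohort_name = "Quadra",
    strata = audit_strata(
      n = c(39, 99, 122, 126, 84, 43, 40),
      target_median = c(46, 56, 64.8, 74, 84, 93, 111.5),
      spread = c(3.5, 3, 3, 3, 3, 3, 8)),
    activity_protocol = list(rule = "fixed", standard = 150,
                             jitter_median = 149.5 / 150,
                             jitter_sdlog = 0.05),
    dlp_model = list(intercept = 4.6831, slope = 0.018659, sdlog = 0.22),
    height_model = list(mean_bmi = 26, sd_bmi = 4, min_bmi = 15, max_bmi = 45),
    height_missing_rate = 419 / 553,
    gender_ratio_male = 319 / 553,
    gender_unknown = 0,
    seed = seed)
}

# Truncated-normal draws by inverse-CDF sampling; exact truncation, no
# rejection loop, deterministic draw count under a seed.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Sample stratified patient weights
#'
#' Draws each stratum's weights from a truncated normal centred on the
#' stratum's target median with the stratum's spread, truncated to the
#' stratum bounds. Per-stratum counts match the spec exactly.
#'
#' @param spec A [cohort_spec()].
#' @return Numeric vector of weights in kg, in stratum order.
#' @export
sample_weights <- function(spec) {
  s <- spec$strata
  unlist(Map(function(n, m, sd, lo, hi) rtruncnorm(n, m, sd, lo, hi),
             s$n, s$target_median, s$spread, s$lower, s$upper),
         use.names = FALSE)
}

#' Protocol injected activity for a patient weight
#'
#' The weight-tiered rule gives the standard activity, switching to the
#' heavy-patient activity above the threshold; the fixed rule gives the
#' standard activity regardless of weight. With `jitter = TRUE` each value
#' is multiplied by a lognormal draw with median `jitter_median`,
#' emulating day-to-day dispensing variation (and, for the conventional
#' cohort, the activity uplift of concurrent clinical-trial protocols that
#' pushes the cohort median above the nominal protocol).
#'
#' @param weight kg, positive; vectorised.
#' @param protocol `activity_protocol` list from a [cohort_spec()].
#' @param jitter Apply multiplicative jitter? With `FALSE` the bare
#'   protocol value is returned.
#' @return Injected activity in MBq.
#' @examples
#' p <- mct_cohort_spec()$activity_protocol
#' protocol_activity(c(70, 95), p, jitter = FALSE)  # 250 300
#' @export
protocol_activity <- function(weight, protocol, jitter = TRUE) {
  stopifnot_number(weight, "weight", positive = TRUE)
  base <- switch(protocol$rule,
    weight_tiered = ifelse(weight > protocol$heavy_threshold,
                           protocol$heavy, protocol$standard),
    fixed = rep(protocol$standard, length(weight)),
    abort_config("unknown activity protocol rule"))
  if (!jitter) return(base)
  base * rlnorm(length(weight), log(protocol$jitter_median),
                protocol$jitter_sdlog)
}

#' Sample dose-length products for patient weights
#'
#' `DLP = exp(intercept + slope x weight + N(0, sdlog))` mGy·cm. The
#' default model coefficients are a least-squares fit of log median DLP
#' against median weight across the seven weight strata of the audited
#' cohorts, so stratum-median CT effective doses land close to the audit's.
#'
#' @param weight kg, positive; vectorised.
#' @param dlp_model `dlp_model` list from a [cohort_spec()].
#' @return DLP in mGy·cm.
#' @export
sample_dlp <- function(weight, dlp_model) {
  stopifnot_number(weight, "weight", positive = TRUE)
  noise <- if (dlp_model$sdlog > 0) rnorm(length(weight), 0, dlp_model$sdlog)
           else 0
  exp(dlp_model$intercept + dlp_model$slope * weight + noise)
}

#' Generate a synthetic patient cohort
#'
#' Draws the full patient table for a spec: stratified weights, protocol
#' activity with jitter, DLP, BMI-derived heights present for exactly
#' `round(n x (1 - height_missing_rate))` patients, and gender at the
#' spec's ratio. Output is byte-identical for a fixed spec + seed; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with columns `patient_id`, `cohort`, `weight`, `height`,
#'   `gender`, `injected_activity`, `dlp`, valid under
#'   [validate_patient_records()].
#' @examples
#' cohort <- generate_cohort(quadra_cohort_spec(seed = 7))
#' nrow(cohort)           # 553
#' sum(!is.na(cohort$height))  # 134
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort_config("`spec` must be a cohort_spec")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  weight <- sample_weights(spec)
  n <- length(weight)
  if (n == 0) abort_petctdose("spec generates an empty cohort",
                              "petctdose_generation_error")
  activity <- protocol_activity(weight, spec$activity_protocol)
  dlp <- sample_dlp(weight, spec$dlp_model)

  hm <- spec$height_model
  bmi <- rtruncnorm(n, hm$mean_bmi, hm$sd_bmi, hm$min_bmi, hm$max_bmi)
  height <- round(100 * sqrt(weight / bmi), 1)
  n_present <- round(n * (1 - spec$height_missing_rate))
  present <- sample.int(n, n_present)
  height[setdiff(seq_len(n), present)] <- NA_real_

  n_known <- n - spec$gender_unknown
  n_male <- round(n_known * spec$gender_ratio_male)
  gender <- sample(c(rep("male", n_male), rep("female", n_known - n_male),
                     rep("unknown", spec$gender_unknown)))

  out <- tibble::tibble(
    patient_id = sprintf("%s-%04d", spec$cohort_name, seq_len(n)),
    cohort = spec$cohort_name,
    weight = weight, height = height, gender = gender,
    injected_activity = activity, dlp = dlp)
  validate_patient_records(out)
  out
}

#' Read cohort specifications from a YAML file
#'
#' Each entry under `cohorts:` carries the [cohort_spec()] fields (`strata`
#' as a list of rows). The packaged `cohort_specs.yaml` mirrors
#' [mct_cohort_spec()] and [quadra_cohort_spec()].
#'
#' @param path YAML file; defaults to the packaged spec file.
#' @param seed Optional integer overriding every spec's seed.
#' @return Named list of `cohort_spec` objects.
#' @export
read_cohort_specs <- function(path = NULL, seed = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_specs.yaml", package = "petctdose")
  }
  if (!file.exists(path)) abort_config(paste0("no such config file: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$cohorts)) abort_config("config file has no `cohorts` section")
  out <- lapply(raw$cohorts, function(cs) {
    strata <- dplyr::bind_rows(lapply(cs$strata, tibble::as_tibble))
    strata$upper[is.infinite(strata$upper) | is.na(strata$upper)] <- Inf
    cohort_spec(
      cohort_name = cs$cohort_name, strata = strata,
      activity_protocol = cs$activity_protocol, dlp_model = cs$dlp_model,
      height_model = cs$height_model,
      height_missing_rate = cs$height_missing_rate,
      gender_ratio_male = cs$gender_ratio_male,
      gender_unknown = if (is.null(cs$gender_unknown)) 0 else cs$gender_unknown,
      seed = if (is.null(seed)) cs$seed else seed)
  })
  names(out) <- vapply(out, function(s) s$cohort_name, character(1))
  out
}

#' Read / write a patient cohort table
#'
#' Comma-separated text with the documented header (`patient_id`, `cohort`,
#' `weight`, `height`, `gender`, `injected_activity`, `dlp`); empty fields
#' are missing heights. Values round-trip at full double precision.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a validated tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such cohort file: ", path))
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if ("height" %in% names(df)) df$height <- as.numeric(df$height)
  validate_patient_records(df)
  df
}

#' @rdname read_cohort
#' @param records Patient table to write.
#' @export
write_cohort <- function(records, path) {
  validate_patient_records(records)
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
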