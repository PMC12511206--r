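# Per-patient effective-dose computations: ICRP reference-model PET dose,
# weight and blood-volume scaling, DLP-to-CT-dose conversion, totals.

#' Dose coefficient scheme for FDG PET and whole-body CT
#'
#' A dose coefficient scheme bundles the ICRP reference models used to
#' convert injected FDG activity to PET effective dose with the
#' dose-length-product (DLP) conversion factor used for the CT component.
#' The default scheme carries the ICRP publication 128 FDG coefficients —
#' 0.019 mSv/MBq for the 70 kg adult, 0.024 mSv/MBq for the 57 kg adult and
#' 0.036 mSv/MBq for the 33 kg child — and the whole-body CT conversion
#' factor of 0.018 mSv per mGy·cm. Patients heavier than 65 kg are assigned
#' the 70 kg adult model, patients of 45–65 kg (closed interval) the 57 kg
#' adult model, and patients lighter than 45 kg the 33 kg child model.
#'
#' @param entries Data frame with columns `model_name`, `model_weight` (kg),
#'   `coefficient` (mSv/MBq), `lower_bound` (kg) and `lower_inclusive`
#'   (logical). A weight is assigned to the entry with the largest lower
#'   bound it exceeds (or meets, when inclusive); entries must therefore be
#'   supplied with strictly increasing lower bounds starting at 0, which
#'   guarantees the rule partitions all positive weights.
#' @param dlp_conversion mSv per mGy·cm used by [ed_ct_from_dlp()].
#' @return An object of class `dose_scheme`.
#' @seealso [read_dose_scheme()] to load a scheme from a YAML file.
#' @examples
#' sch <- default_dose_scheme()
#' assign_reference_model(c(44, 45, 65, 66), sch)
#' @export
dose_scheme <- function(entries, dlp_conversion = 0.018) {
  entries <- tibble::as_tibble(entries)
  required <- c("model_name", "model_weight", "coefficient",
                "lower_bound", "lower_inclusive")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    abort_config(paste0("dose scheme entries lack column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  stopifnot_number(entries$model_weight, "model_weight", positive = TRUE)
  stopifnot_number(entries$coefficient, "coefficient", positive = TRUE)
  stopifnot_number(entries$lower_bound, "lower_bound", nonneg = TRUE)
  entries <- entries[order(entries$lower_bound), ]
  if (entries$lower_bound[1] != 0) {
    abort_config("the first entry must have lower_bound 0 so all positive weights are covered")
  }
  if (any(diff(entries$lower_bound) <= 0)) {
    abort_config("entry lower bounds must be strictly increasing (no overlap)")
  }
  stopifnot_number(dlp_conversion, "dlp_conversion", positive = TRUE)
  structure(list(entries = entries, dlp_conversion = dlp_conversion),
            class = "dose_scheme")
}

#' @rdname dose_scheme
#' @export
default_dose_scheme <- function() {
  dose_scheme(
    entries = tibble::tibble(
      model_name      = c("33 kg child", "57 kg adult", "70 kg adult"),
      model_weight    = c(33, 57, 70),
      coefficient     = c(0.036, 0.024, 0.019),
      lower_bound     = c(0, 45, 65),
      lower_inclusive = c(FALSE, TRUE, FALSE)),
    dlp_conversion = 0.018)
}

#' Read a dose coefficient scheme from a YAML file
#'
#' The file holds a `dlp_conversion` scalar and an `entries` list, each
#' entry with `model_name`, `model_weight`, `coefficient`, `lower_bound`
#' and `lower_inclusive` fields. See
#' `system.file("extdata", "dose_scheme.yaml", package = "petctdose")`.
#'
#' @param path Path to a YAML file.
#' @return A `dose_scheme`.
#' @export
read_dose_scheme <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such config file: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$entries)) abort_config("config file has no `entries` section")
  entries <- dplyr::bind_rows(lapply(raw$entries, tibble::as_tibble))
  dose_scheme(entries,
              dlp_conversion = if (is.null(raw$dlp_conversion)) 0.018
                               else raw$dlp_conversion)
}

#' @export
print.dose_scheme <- function(x, ...) {
  cat("<dose_scheme> DLP conversion:", x$dlp_conversion, "mSv/(mGy cm)\n")
  print(x$entries)
  invisible(x)
}

#' Assign the ICRP reference model for a patient weight
#'
#' @param weight Patient weight(s) in kg; must be strictly positive.
#' @param scheme A [dose_scheme()].
#' @return A tibble with one row per weight: `model_name`, `model_weight`
#'   (kg) and `coefficient` (mSv/MBq).
#' @examples
#' assign_reference_model(73)$coefficient  # 0.019
#' @export
assign_reference_model <- function(weight, scheme = default_dose_scheme()) {
  stopifnot_number(weight, "weight", positive = TRUE)
  e <- scheme$entries
  idx <- vapply(weight, function(w) {
    hits <- ifelse(e$lower_inclusive, w >= e$lower_bound, w > e$lower_bound)
    max(which(hits))
  }, integer(1))
  tibble::tibble(model_name = e$model_name[idx],
                 model_weight = e$model_weight[idx],
                 coefficient = e$coefficient[idx])
}

#' PET effective dose from injected activity
#'
#' `ED_PET = injected activity (MBq) x dose coefficient (mSv/MBq)`.
#'
#' @param injected_activity MBq, non-negative.
#' @param coefficient mSv/MBq, strictly positive.
#' @return Effective dose in mSv.
#' @examples
#' ed_pet(400, 0.019)  # 7.6 mSv
#' @export
ed_pet <- function(injected_activity, coefficient) {
  stopifnot_number(injected_activity, "injected_activity", nonneg = TRUE)
  stopifnot_number(coefficient, "coefficient", positive = TRUE)
  injected_activity * coefficient
}

#' Scale a PET effective dose to the patient's weight
#'
#' `ED_PET-WS = ED_PET x model weight / patient weight`: the reference-model
#' dose is rescaled by the ratio of the assigned ICRP model weight to the
#' actual patient weight.
#'
#' @param ed_pet Unscaled PET effective dose in mSv.
#' @param model_weight ICRP reference-model weight in kg.
#' @param patient_weight Patient weight in kg, strictly positive.
#' @return Weight-scaled effective dose in mSv.
#' @export
ed_pet_weight_scaled <- function(ed_pet, model_weight, patient_weight) {
  stopifnot_number(ed_pet, "ed_pet", nonneg = TRUE)
  stopifnot_number(model_weight, "model_weight", positive = TRUE)
  stopifnot_number(patient_weight, "patient_weight", positive = TRUE)
  ed_pet * model_weight / patient_weight
}

#' Body mass index from weight and height
#'
#' Height is stored in cm (the clinical-records convention) and converted to
#' metres internally. A missing or non-positive height yields `NA` rather
#' than an error: downstream blood-volume quantities are simply absent for
#' such patients.
#'
#' @param weight kg, strictly positive.
#' @param height cm; `NA` or non-positive values give `NA`.
#' @return BMI in kg/m2, `NA` where height is unavailable.
#' @export
body_mass_index <- function(weight, height) {
  stopifnot_number(weight, "weight", positive = TRUE)
  if (is.logical(height) && all(is.na(height))) height <- as.numeric(height)
  if (!is.numeric(height)) abort_invalid("`height` must be numeric")
  h <- ifelse(!is.na(height) & height > 0, height / 100, NA_real_)
  weight / h^2
}

#' Indexed blood volume from body mass index
#'
#' `IBV = 70 (ml/kg) / sqrt(BMI / 22)`: per-kg blood volume relative to a
#' reference BMI of 22 kg/m2, at which the indexed blood volume equals the
#' reference 70 ml/kg.
#'
#' @param bmi kg/m2, strictly positive; `NA` propagates.
#' @return Indexed blood volume in ml/kg.
#' @examples
#' indexed_blood_volume(22)  # 70
#' @export
indexed_blood_volume <- function(bmi) {
  stopifnot_number(bmi, "bmi", positive = TRUE, allow_na = TRUE)
  70 / sqrt(bmi / 22)
}

#' Scale a PET effective dose to the patient's blood volume
#'
#' `ED_PET-BV = ED_PET x indexed blood volume / 70 (ml/kg)`. Identity at the
#' reference blood volume of 70 ml/kg (BMI 22).
#'
#' @param ed_pet Unscaled PET effective dose in mSv.
#' @param indexed_bv ml/kg, strictly positive; `NA` propagates.
#' @return Blood-volume-scaled effective dose in mSv.
#' @export
ed_pet_blood_volume_scaled <- function(ed_pet, indexed_bv) {
  stopifnot_number(ed_pet, "ed_pet", nonneg = TRUE)
  stopifnot_number(indexed_bv, "indexed_bv", positive = TRUE, allow_na = TRUE)
  ed_pet * indexed_bv / 70
}

#' CT effective dose from the dose-length product
#'
#' `ED_CT = DLP (mGy cm) x conversion (mSv per mGy cm)`. The default
#' whole-body conversion factor is 0.018 mSv per mGy·cm.
#'
#' @param dlp Dose-length product in mGy·cm, non-negative.
#' @param conversion mSv per mGy·cm.
#' @return CT effective dose in mSv.
#' @examples
#' ed_ct_from_dlp(427.78)  # about 7.7 mSv
#' @export
ed_ct_from_dlp <- function(dlp, conversion = 0.018) {
  stopifnot_number(dlp, "dlp", nonneg = TRUE)
  stopifnot_number(conversion, "conversion", positive = TRUE)
  dlp * conversion
}

#' Total effective dose of a PET/CT examination
#'
#' `ED_total = ED_CT + ED_PET`, evaluated once per PET dose variant
#' (reference-model, weight-scaled, blood-volume-scaled).
#'
#' @param ed_ct CT effective dose in mSv.
#' @param ed_pet_variant PET effective dose (any variant) in mSv; `NA`
#'   propagates so a missing blood-volume dose gives a missing total.
#' @return Total effective dose in mSv.
#' @export
ed_total <- function(ed_ct, ed_pet_variant) {
  stopifnot_number(ed_ct, "ed_ct", nonneg = TRUE)
  stopifnot_number(ed_pet_variant, "ed_pet_variant", nonneg = TRUE,
                   allow_na = TRUE)
  ed_ct + ed_pet_variant
}

#' Validate a table of patient records
#'
#' Checks the documented schema: columns `patient_id`, `cohort`, `weight`,
#' `injected_activity`, `dlp` (with optional `height` and `gender`), weight
#' and any recorded height strictly positive, activity and DLP non-negative.
#' On failure a validation error lists the offending row numbers.
#'
#' @param records Data frame of patient records.
#' @return The records, invisibly, when valid.
#' @export
validate_patient_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_schema("patient records must be a non-empty data frame")
  }
  required <- c("patient_id", "cohort", "weight", "injected_activity", "dlp")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort_schema(paste0("patient table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  bad <- !is.finite(records$weight) | records$weight <= 0 |
    !is.finite(records$injected_activity) | records$injected_activity < 0 |
    !is.finite(records$dlp) | records$dlp < 0
  if ("height" %in% names(records)) {
    bad <- bad | (!is.na(records$height) & records$height <= 0)
  }
  if (any(bad)) {
    abort_schema(paste0("invalid patient record(s) in row(s): ",
                        paste(which(bad), collapse = ", ")))
  }
  invisible(records)
}

#' Effective doses for a single patient
#'
#' Composes the dosimetry chain for one patient: reference-model assignment,
#' PET dose, weight scaling, BMI / indexed blood volume / blood-volume
#' scaling (absent when height is missing), CT dose from DLP, and the three
#' totals.
#'
#' @param record A list or one-row data frame with `weight` (kg),
#'   `injected_activity` (MBq), `dlp` (mGy·cm) and optionally `height` (cm).
#' @param scheme A [dose_scheme()].
#' @return A list of class `dose_result` with elements `model_name`,
#'   `ed_pet`, `ed_pet_ws`, `ed_pet_bv`, `ed_ct`, `ed_total_icrp`,
#'   `ed_total_ws`, `ed_total_bv` (blood-volume elements are `NA` when
#'   height is missing).
#' @examples
#' dose_result_for_patient(
#'   list(weight = 70, height = 178.4, injected_activity = 150, dlp = 420))
#' @export
dose_result_for_patient <- function(record, scheme = default_dose_scheme()) {
  height <- if (!is.null(record$height)) record$height else NA_real_
  model <- assign_reference_model(record$weight, scheme)
  pet <- ed_pet(record$injected_activity, model$coefficient)
  ws <- ed_pet_weight_scaled(pet, model$model_weight, record$weight)
  bmi <- body_mass_index(record$weight, height)
  bv <- ed_pet_blood_volume_scaled(pet, indexed_blood_volume(bmi))
  ct <- ed_ct_from_dlp(record$dlp, scheme$dlp_conversion)
  structure(list(
    model_name = model$model_name,
    ed_pet = pet, ed_pet_ws = ws, ed_pet_bv = bv, ed_ct = ct,
    ed_total_icrp = ed_total(ct, pet),
    ed_total_ws = ed_total(ct, ws),
    ed_total_bv = ed_total(ct, bv)), class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat("<dose_result>", x$model_name, "model\n")
  v <- unlist(x[-1])
  cat(paste0("  ", format(names(v), width = 14), sprintf("%8.3f mSv", v),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Effective doses for a whole cohort
#'
#' Vectorised version of [dose_result_for_patient()]: validates the record
#' table and appends the dose columns. Patients without a recorded height
#' get `NA` for the blood-volume-scaled dose and its total, and are later
#' excluded (with reduced n) from blood-volume summaries.
#'
#' @param records Patient table satisfying [validate_patient_records()].
#' @param scheme A [dose_scheme()].
#' @return The input tibble with columns `model_name`, `ed_pet`,
#'   `ed_pet_ws`, `ed_pet_bv`, `ed_ct`, `ed_total_icrp`, `ed_total_ws`,
#'   `ed_total_bv` appended.
#' @export
compute_doses <- function(records, scheme = default_dose_scheme()) {
  validate_patient_records(records)
  records <- tibble::as_tibble(records)
  height <- if ("height" %in% names(records)) records$height
            else rep(NA_real_, nrow(records))
  model <- assign_reference_model(records$weight, scheme)
  pet <- ed_pet(records$injected_activity, model$coefficient)
  ws <- ed_pet_weight_scaled(pet, model$model_weight, records$weight)
  bv <- ed_pet_blood_volume_scaled(
    pet, indexed_blood_volume(body_mass_index(records$weight, height)))
  ct <- ed_ct_from_dlp(records$dlp, scheme$dlp_conversion)
  dplyr::bind_cols(records, tibble::tibble(
    model_name = model$model_name,
    ed_pet = pet, ed_pet_ws = ws, ed_pet_bv = bv, ed_ct = ct,
    ed_total_icrp = ed_total(ct, pet),
    ed_total_ws = ed_total(ct, ws),
    ed_total_bv = ed_total(ct, bv)))
}
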