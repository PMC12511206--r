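test_that("reference-model assignment follows the weight thresholds", {
  cases <- list(
    list(w = 73, name = "70 kg adult", coef = 0.019),
    list(w = 66, name = "70 kg adult", coef = 0.019),
    list(w = 65, name = "57 kg adult", coef = 0.024),  # closed upper bound
    list(w = 45, name = "57 kg adult", coef = 0.024),  # closed lower bound
    list(w = 44.0, name = "33 kg child", coef = 0.036),
    list(w = 0.5, name = "33 kg child", coef = 0.036))
  for (cs in cases) {
    m <- assign_reference_model(cs$w)
    expect_identical(m$model_name, cs$name)
    expect_identical(m$coefficient, cs$coef)
  }
  expect_error(assign_reference_model(0), class = "petctdose_invalid_input")
  expect_error(assign_reference_model(-3), class = "petctdose_invalid_input")
})

test_that("model assignment partitions all positive weights", {
  set.seed(11)
  w <- c(runif(500, 0.1, 200), 45, 65, 44.999, 65.001)
  m <- assign_reference_model(w)
  expect_equal(nrow(m), length(w))
  expect_false(any(is.na(m$coefficient)))
  # each weight maps to exactly one model and boundary cases go to 57 kg
  expect_identical(assign_reference_model(45)$model_weight, 57)
  expect_identical(assign_reference_model(65)$model_weight, 57)
})

test_that("PET dose reproduces the national reference-level worked doses", {
  expect_equal(ed_pet(400, 0.019), 7.6)
  expect_equal(signif(ed_pet(592, 0.019), 3), 11.2)
  expect_equal(ed_pet(270, 0.019), 5.13)
  expect_equal(ed_pet(0, 0.019), 0)
  expect_error(ed_pet(-1, 0.019), class = "petctdose_invalid_input")
})

test_that("PET dose and CT dose are linear in their inputs", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(1, 0, 600); k <- runif(1, 0, 5)
    expect_equal(ed_pet(k * a, 0.019), k * ed_pet(a, 0.019))
    expect_equal(ed_ct_from_dlp(k * a), k * ed_ct_from_dlp(a))
  }
})

test_that("weight scaling matches direct evaluation and decreases in weight", {
  expect_equal(ed_pet_weight_scaled(5.7, 70, 70), 5.7)
  expect_equal(ed_pet_weight_scaled(7.6, 70, 95), 5.6)
  expect_equal(ed_pet_weight_scaled(3.6, 33, 44), 2.7)
  w <- seq(40, 140, by = 5)
  expect_true(all(diff(ed_pet_weight_scaled(5, 70, w)) < 0))
  expect_error(ed_pet_weight_scaled(5, 70, 0), class = "petctdose_invalid_input")
})

test_that("BMI is computed from cm heights and absent when height missing", {
  expect_equal(round(body_mass_index(70, 178.4), 2), 21.99)
  expect_equal(body_mass_index(88, 200), 22)
  expect_true(is.na(body_mass_index(70, NA)))
  expect_true(is.na(body_mass_index(70, 0)))
  expect_error(body_mass_index(0, 170), class = "petctdose_invalid_input")
})

test_that("indexed blood volume closes against its defining relation", {
  expect_equal(indexed_blood_volume(22), 70)
  expect_equal(indexed_blood_volume(88), 35)
  expect_equal(indexed_blood_volume(30.8), 70 / sqrt(1.4), tolerance = 1e-12)
  bmi <- seq(5.05, 99.95, by = 0.35)
  expect_true(all(abs(indexed_blood_volume(bmi) * sqrt(bmi / 22) - 70) < 1e-9))
  expect_true(all(diff(indexed_blood_volume(bmi)) < 0))  # strictly decreasing
  expect_error(indexed_blood_volume(-1), class = "petctdose_invalid_input")
})

test_that("blood-volume scaling is identity at the 70 ml/kg reference", {
  expect_equal(ed_pet_blood_volume_scaled(5, 70), 5)
  expect_equal(ed_pet_blood_volume_scaled(5, 35), 2.5)
  expect_equal(ed_pet_blood_volume_scaled(2.85, 59.16), 2.409, tolerance = 1e-3)
})

test_that("CT dose conversion from DLP", {
  expect_equal(ed_ct_from_dlp(0), 0)
  expect_equal(ed_ct_from_dlp(1000), 18)
  expect_equal(round(ed_ct_from_dlp(427.78), 1), 7.7)
  expect_error(ed_ct_from_dlp(-5), class = "petctdose_invalid_input")
})

test_that("per-patient dose result composes the chain and respects missingness", {
  r <- dose_result_for_patient(
    list(weight = 70, height = 178.4, injected_activity = 150, dlp = 420))
  expect_equal(r$ed_pet, 2.85)
  expect_equal(r$ed_pet_ws, 2.85)
  expect_equal(r$ed_pet_bv, 2.85, tolerance = 1e-3)
  expect_equal(r$ed_ct, 7.56)
  expect_identical(r$model_name, "70 kg adult")
  # totals equal their addends to floating tolerance
  expect_equal(r$ed_total_icrp, r$ed_ct + r$ed_pet, tolerance = 1e-12)
  expect_equal(r$ed_total_ws, r$ed_ct + r$ed_pet_ws, tolerance = 1e-12)
  expect_equal(r$ed_total_bv, r$ed_ct + r$ed_pet_bv, tolerance = 1e-12)

  child <- dose_result_for_patient(
    list(weight = 44, injected_activity = 150, dlp = 100))
  expect_equal(child$ed_pet, 5.4)
  expect_true(is.na(child$ed_pet_bv) && is.na(child$ed_total_bv))
  expect_false(anyNA(c(child$ed_pet, child$ed_pet_ws, child$ed_ct,
                       child$ed_total_icrp, child$ed_total_ws)))
})

test_that("cohort-level doses match the per-patient results row by row", {
  tab <- compute_doses(toy_cohort())
  for (i in seq_len(nrow(tab))) {
    one <- dose_result_for_patient(as.list(tab[i, ]))
    for (f in c("ed_pet", "ed_pet_ws", "ed_pet_bv", "ed_ct",
                "ed_total_icrp", "ed_total_ws", "ed_total_bv")) {
      expect_equal(tab[[f]][i], one[[f]])
    }
  }
  expect_true(is.na(tab$ed_pet_bv[2]))  # the patient with no height
})

test_that("record validation reports offending rows", {
  bad <- toy_cohort()
  bad$weight[2] <- -1
  bad$dlp[4] <- -10
  err <- tryCatch(validate_patient_records(bad), error = identity)
  expect_s3_class(err, "petctdose_validation_error")
  expect_match(conditionMessage(err), "2, 4")
  expect_error(validate_patient_records(bad[0, ]),
               class = "petctdose_validation_error")
})

test_that("a dose scheme is loadable from the packaged config file", {
  path <- system.file("extdata", "dose_scheme.yaml", package = "petctdose")
  sch <- read_dose_scheme(path)
  expect_s3_class(sch, "dose_scheme")
  expect_equal(sch$dlp_conversion, 0.018)
  expect_equal(assign_reference_model(73, sch)$coefficient, 0.019)
  expect_equal(sch$entries$coefficient,
               default_dose_scheme()$entries$coefficient)
  expect_error(read_dose_scheme("no/such/file.yaml"),
               class = "petctdose_config_error")
})
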