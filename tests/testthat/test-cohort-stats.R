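test_that("weight categories are assigned by half-open 10-kg bins", {
  expect_identical(assign_weight_category(46), "<50")
  expect_identical(assign_weight_category(99.9), "90–99")
  expect_identical(assign_weight_category(100), ">100")
  expect_identical(assign_weight_category(49.999), "<50")
  expect_identical(assign_weight_category(50), "50–59")
  expect_error(assign_weight_category(0), class = "petctdose_invalid_input")
})

test_that("every weight falls in exactly one stratum and counts add up", {
  set.seed(41)
  w <- runif(400, 30, 150)
  cat <- assign_weight_category(w)
  expect_false(anyNA(cat))
  counts <- table(factor(cat, levels = weight_category_scheme()$label))
  expect_equal(sum(counts), length(w))
})

test_that("median and quartiles interpolate between order statistics", {
  expect_equal(median_iqr(c(1, 2, 3)), list(median = 2, q1 = 1.5, q3 = 2.5))
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               list(median = 2.5, q1 = 1.75, q3 = 3.25))
  expect_equal(median_iqr(5), list(median = 5, q1 = 5, q3 = 5))
  s <- median_iqr(rnorm(50))
  expect_true(s$q1 <= s$median && s$median <= s$q3)
  expect_error(median_iqr(numeric(0)), class = "petctdose_empty_input")
})

test_that("percentage difference matches the printed-median arithmetic", {
  expect_equal(round(percent_difference(303, 149.5), 1), -50.7)
  expect_equal(round(percent_difference(73, 70), 1), -4.1)
  expect_equal(percent_difference(7, 7), 0)
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    expect_equal(sign(percent_difference(a, b)), sign(b - a))
  }
  expect_error(percent_difference(0, 5), class = "petctdose_invalid_input")
})

test_that("Mann-Whitney exact p matches the enumeration oracle", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  set.seed(43)
  for (i in 1:60) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    pooled <- sample(seq_len(50), na + nb)  # tie-free
    a <- pooled[seq_len(na)]; b <- pooled[-seq_len(na)]
    r <- mann_whitney_u(a, b)
    expect_equal(r$U, brute_u(a, b))
    expect_equal(r$p_value, brute_mwu_p(a, b), tolerance = 1e-12)
  }
})

test_that("tied samples get midrank U and the pairing identity holds", {
  r <- mann_whitney_u(c(1, 1, 2), c(1, 2, 2))
  expect_equal(r$U, brute_u(c(1, 1, 2), c(1, 2, 2)))
  set.seed(44)
  for (i in 1:20) {
    a <- sample(1:6, sample(3:10, 1), replace = TRUE)
    b <- sample(1:6, sample(3:10, 1), replace = TRUE)
    ua <- mann_whitney_u(a, b)$U
    ub <- mann_whitney_u(b, a)$U
    expect_equal(ua + ub, length(a) * length(b))  # with 0.5-credit ties
  }
})

test_that("degenerate and identical samples give non-significant p", {
  expect_gt(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 0.8)
  expect_equal(mann_whitney_u(c(2, 2), c(2, 2, 2))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "petctdose_empty_input")
})

test_that("CT dose proportion is a scale-free percentage", {
  expect_equal(ct_dose_proportion(5, 10), 50)
  expect_equal(round(ct_dose_proportion(7.56, 10.41), 1), 72.6)
  expect_equal(ct_dose_proportion(0, 4), 0)
  set.seed(45)
  for (i in 1:10) {
    ct <- runif(1, 0, 5); tot <- ct + runif(1, 0.1, 5); k <- runif(1, 0.1, 9)
    expect_equal(ct_dose_proportion(k * ct, k * tot),
                 ct_dose_proportion(ct, tot), tolerance = 1e-12)
  }
  expect_error(ct_dose_proportion(5, 0), class = "petctdose_invalid_input")
  expect_error(ct_dose_proportion(6, 5), class = "petctdose_invalid_input")
})

test_that("single-patient cohorts compare to their own values", {
  a <- toy_cohort("A")[1, ]
  b <- toy_cohort("B")[3, ]
  cmp <- compare_cohorts(a, b)
  row <- cmp[cmp$quantity == "weight" & cmp$stratum == "ALL", ]
  expect_equal(row$median_a, 70)
  expect_equal(row$median_b, 95)
  act <- cmp[cmp$quantity == "injected_activity" & cmp$stratum == "ALL", ]
  expect_equal(act$median_a, 150)
  expect_equal(act$median_b, 300)
  expect_equal(act$percent_difference, 100)
})

test_that("comparison covers every quantity and stratum with consistent n", {
  set.seed(46)
  m <- generate_cohort(mct_cohort_spec(seed = 5))
  q <- generate_cohort(quadra_cohort_spec(seed = 6))
  cmp <- compare_cohorts(m, q)
  expect_equal(nrow(cmp), 9 * 8)  # 9 quantities x (ALL + 7 strata)
  all_rows <- cmp[cmp$stratum == "ALL", ]
  expect_true(all(all_rows$n_a[all_rows$quantity %in%
    c("weight", "injected_activity", "ed_ct", "ed_pet")] == 484))
  # blood-volume rows report reduced n from height missingness
  bv <- all_rows[all_rows$quantity == "ed_pet_bv", ]
  expect_equal(bv$n_a, 387)
  expect_equal(bv$n_b, 134)
  # stratum counts sum to the cohort size for fully observed quantities
  w <- cmp[cmp$quantity == "weight" & cmp$stratum != "ALL", ]
  expect_equal(sum(w$n_a), 484)
  expect_equal(sum(w$n_b), 553)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))
})

test_that("cohorts with no heights yield empty blood-volume statistics", {
  a <- toy_cohort("A"); a$height <- NA_real_
  b <- toy_cohort("B"); b$height <- NA_real_
  cmp <- compare_cohorts(a, b)
  bv <- cmp[cmp$quantity == "ed_pet_bv", ]
  expect_true(all(bv$n_a == 0 & bv$n_b == 0 |
                    (bv$stratum != "ALL" & bv$n_a == 0)))
  all_bv <- bv[bv$stratum == "ALL", ]
  expect_true(is.na(all_bv$median_a) && is.na(all_bv$median_b))
  expect_true(is.na(all_bv$p_value))
})
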