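test_that("measurement schema has the 45/52/40 grouping with unique names", {
  sch <- measurement_schema()
  expect_length(sch$skeletal_names, 45L)
  expect_length(sch$dental_names, 52L)
  expect_length(sch$soft_tissue_names, 40L)
  expect_length(sch$all_names, 137L)
  expect_false(anyDuplicated(sch$all_names) > 0)
})

test_that("empty cohort and determinism contracts hold", {
  expect_length(sample_cohort(cohort_config(n = 0, seed = 1)), 0L)
  a <- sample_cohort(cohort_config(n = 25, seed = 9))
  b <- sample_cohort(cohort_config(n = 25, seed = 9))
  expect_identical(a, b)
  c <- sample_cohort(cohort_config(n = 25, seed = 10))
  expect_false(identical(a, c))
})

test_that("cohort marginals are recovered at large n", {
  n <- 10000L
  ch <- sample_cohort(cohort_config(n = n, seed = 1))
  ages <- vapply(ch, `[[`, numeric(1), "age_years")
  expect_true(all(ages >= 18 & ages <= 35))
  # sample mean age within the spec'd window around the published mean
  expect_lt(abs(mean(ages) - 22.7), 0.15)

  p3_target <- 53.9 / (40.9 + 53.9)
  is_iii <- vapply(ch, function(r) "ClassIII" %in% r$deformity_labels,
                   logical(1))
  is_ii <- vapply(ch, function(r) "ClassII" %in% r$deformity_labels,
                  logical(1))
  expect_lt(abs(mean(is_iii) - p3_target), 0.02)
  # sagittal classes are exclusive and exhaustive
  expect_true(all(xor(is_iii, is_ii)))

  # remaining configured frequencies/means within 3 standard errors
  se_p <- function(p) sqrt(p * (1 - p) / n)
  fem <- mean(vapply(ch, `[[`, character(1), "sex") == "female")
  expect_lt(abs(fem - 0.571), 3 * se_p(0.571))
  asym <- mean(vapply(ch, function(r) "Asymmetry" %in% r$deformity_labels,
                      logical(1)))
  expect_lt(abs(asym - 0.380), 3 * se_p(0.380))
  vert <- mean(vapply(ch, function(r)
    "VerticalDiscrepancy" %in% r$deformity_labels, logical(1)))
  expect_lt(abs(vert - 0.274), 3 * se_p(0.274))

  anb3 <- vapply(ch[is_iii], `[[`, numeric(1), "anb_deg")
  expect_lt(abs(mean(anb3) - (-2.8)), 3 * 2.1 / sqrt(length(anb3)))
  anb2 <- vapply(ch[is_ii], `[[`, numeric(1), "anb_deg")
  expect_lt(abs(mean(anb2) - 5.9), 3 * 1.8 / sqrt(length(anb2)))
})

test_that("record validation rejects invalid configurations by field", {
  expect_error(patient_record("x", 40, "female", "ClassII", 5), "age_years")
  expect_error(patient_record("x", 25, "female", character(), 5),
               "deformity_labels")
  expect_error(patient_record("x", 25, "female", c("ClassII", "ClassIII"), 5),
               "co-occur")
  expect_error(cohort_config(n = -1), "n")
  expect_error(cohort_config(sex_female_prob = 1.5), "sex_female_prob")
  expect_error(cohort_config(age_sd = -1), "age_sd")
})

test_that("sampled states are complete, record-consistent and deterministic", {
  sch <- measurement_schema()
  for (rec in list(class_iii_record(-2.8), class_ii_record(5.9))) {
    st <- sample_patient_state(rec, sch, seed = 5)
    expect_identical(st$skeletal$ceph[["ANB"]], rec$anb_deg)
    m <- state_measurements(st, sch)
    expect_length(m, 137L)
    expect_setequal(names(m), sch$all_names)
    expect_true(all(is.finite(m)))
    expect_equal(nrow(validate_state(st)), 0L)
    st2 <- sample_patient_state(rec, sch, seed = 5)
    expect_identical(st, st2)
  }
  # Class III records get a negative-ANB skeletal configuration
  st3 <- sample_patient_state(class_iii_record(-2.8), sch, seed = 5)
  expect_lt(st3$skeletal$ceph[["ANB"]], 0)
  expect_identical(st3$skeletal$occlusal_class, "III")
})

test_that("validate_state names field, value and scale of violations", {
  st <- sample_patient_state(class_iii_record(), seed = 1)
  st$soft_tissue$facial_harmony <- 12
  v <- validate_state(st)
  expect_equal(nrow(v), 1L)
  expect_match(v$field, "facial_harmony")
  expect_match(v$allowed, "0, 10")

  st2 <- sample_patient_state(class_iii_record(), seed = 1)
  st2$treatment_status$relapse_risk <- -0.1
  v2 <- validate_state(st2)
  expect_match(v2$field, "relapse_risk")
  expect_match(v2$allowed, "0, 1")
})

test_that("cohort JSON-lines round-trips and feature table is complete", {
  ch <- small_cohort(4)
  f <- tempfile(fileext = ".jsonl")
  write_cohort(ch, f)
  back <- read_cohort(f)
  expect_equal(length(back), 4L)
  expect_equal(back[[2]]$anb_deg, ch[[2]]$anb_deg)
  expect_equal(back[[2]]$deformity_labels, ch[[2]]$deformity_labels)

  csv <- tempfile(fileext = ".csv")
  df <- write_feature_table(ch, csv)
  expect_equal(nrow(df), 4L)
  expect_equal(ncol(df), 137L + 3L)
  expect_true(file.exists(csv))
})
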