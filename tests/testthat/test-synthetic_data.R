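test_that("generation is seed-deterministic", {
  cfg <- sim_config(seed = 99, sources = list(
    sim_source_spec("s", dialect = "A", n_icus = 2, patients_per_icu = 40)))
  a <- generate_store(cfg)
  b <- generate_store(cfg)
  for (tab in names(a$sources$s$store)) {
    expect_equal(a$sources$s$store[[tab]], b$sources$s$store[[tab]], info = tab)
  }
  expect_equal(a$truth, b$truth)
})

test_that("generated stores pass validation and deaths lie inside the ICU stay", {
  study <- small_study()
  for (s in study$sources) {
    expect_equal(nrow(validate_store(s$store)), 0)
    tr <- s$truth
    dd <- s$store$death
    hit <- match(tr$person_id[tr$icu_death], dd$person_id)
    expect_true(all(!is.na(hit)))
    dt <- dd$death_datetime[hit]
    expect_true(all(dt >= tr$icu_admit[tr$icu_death] &
                      dt <= tr$icu_discharge[tr$icu_death]))
  }
})

test_that("realized mortality is within 3 binomial SEs of the mean true risk", {
  tr <- simulate_truth(2000, seed = 808, multiplier = 1)
  p <- mean(tr$p_death)
  se <- sqrt(p * (1 - p) / nrow(tr))
  expect_lt(abs(mean(tr$icu_death) - p), 3 * se)
  # expected deaths recorded per ICU match the sum of risks
  study <- small_study()
  icu <- study$icu_truth
  manual <- study$truth |>
    dplyr::filter(.data$in_cohort) |>
    dplyr::group_by(.data$source, .data$icu_id) |>
    dplyr::summarise(expected = sum(.data$risk),
                     observed = sum(.data$icu_death), .groups = "drop")
  expect_equal(icu$expected, manual$expected)
  expect_equal(icu$observed, manual$observed)
})

test_that("the two dialects differ only where the registries' builds differ", {
  mk <- function(d) sim_config(seed = 31, sources = list(
    sim_source_spec("s", dialect = d, n_icus = 2, patients_per_icu = 60,
                    missingness = list(mechanism = "MCAR", rate = 0,
                                       variables = character()))))
  sa <- generate_store(mk("A"))$sources$s
  sb <- generate_store(mk("B"))$sources$s
  # identical truth (same patients, same physiology, same outcomes)
  expect_equal(sa$truth, sb$truth)
  # leukocytes coded 3000905 in A, 3003282 in B; values identical
  ma <- sa$store$measurement
  mb <- sb$store$measurement
  expect_true(any(ma$measurement_concept_id == 3000905))
  expect_false(any(ma$measurement_concept_id == 3003282))
  expect_true(any(mb$measurement_concept_id == 3003282))
  expect_false(any(mb$measurement_concept_id == 3000905))
  swap <- mb$measurement_concept_id
  swap[swap == 3003282L] <- 3000905L
  expect_equal(dplyr::mutate(mb, measurement_concept_id = swap), ma)
  # comorbidities move between condition_occurrence and observation
  expect_true(any(sa$store$condition_occurrence$condition_concept_id == 4064161))
  expect_false(any(sb$store$condition_occurrence$condition_concept_id == 4064161))
  expect_true(any(sb$store$observation$observation_concept_id == 4064161))
})

test_that("MCAR deletion hits the configured rate within binomial tolerance", {
  cfg <- sim_config(seed = 55, sources = list(
    sim_source_spec("s", dialect = "A", n_icus = 4, patients_per_icu = 400,
                    missingness = list(mechanism = "MCAR", rate = 0.3,
                                       variables = lab_variables()))))
  st <- generate_store(cfg)$sources$s
  sel <- select_cohort(st$store, st$config)
  wide <- extract_first24h(st$store, sel$cohort, st$config)
  n <- nrow(wide)
  for (v in lab_variables()) {
    frac <- mean(is.na(wide[[paste0(v, "_highest")]]))
    expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  }
})

test_that("rate 0 leaves the store unchanged; MAR deletes sicker patients' values", {
  study <- small_study()
  s <- study$sources$regA
  same <- apply_missingness(s$store, s$truth,
                            list(mechanism = "MCAR", rate = 0,
                                 variables = lab_variables()), seed = 1)
  expect_equal(same$measurement, s$store$measurement)

  masked <- apply_missingness(s$store, s$truth,
                              list(mechanism = "MAR", rate = 0.35,
                                   variables = "creatinine"), seed = 9)
  cr <- icubench:::dialect_concepts("A")$concepts$creatinine
  before <- unique(s$store$measurement$visit_detail_id[
    s$store$measurement$measurement_concept_id == cr])
  after <- unique(masked$measurement$visit_detail_id[
    masked$measurement$measurement_concept_id == cr])
  deleted <- setdiff(before, after)
  expect_gt(length(deleted), 10)
  z <- s$truth$z[match(deleted, s$truth$visit_detail_id)]
  z_kept <- s$truth$z[match(after, s$truth$visit_detail_id)]
  expect_gt(mean(z), mean(z_kept))   # deleted records come from sicker patients
})

test_that("with multiplier m the realized SMR against true risks approaches m", {
  for (m in c(0.7, 1.5)) {
    tr <- simulate_truth(4000, seed = 300 + m * 10, multiplier = m)
    E <- sum(tr$risk)
    O <- sum(tr$icu_death)
    expect_lt(abs(O / E - m), 3 * sqrt(O) / E)
  }
})

test_that("invalid configurations fail with the offending field named", {
  expect_error(sim_source_spec("s", smr_multipliers = -1), "smr_multipliers")
  expect_error(sim_config(category_probs = c(nonop_sepsis = 0.4)), "simplex")
  expect_error(sim_config(admission_window = as.Date(c("2022-01-01", "2020-01-01"))),
               "window")
  expect_error(simulate_truth(10, 1, category_probs = c(not_a_category = 1)),
               "unknown categor")
})
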