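# Hand-built mini OMOP store exercising the cohort boundary rules and the
# worst-value window, plus a lazily generated small synthetic study shared
# across tests.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# Persons (admissions all in 2020 unless noted):
#  1: age 17 at admission (eligible boundary), full measurement fixture,
#     death 1h before ICU discharge -> ICU death, LOS 2.5 days
#  2: age 16 -> excluded
#  3: adult, two ICU stays in one hospital visit -> second stay dropped;
#     death 2 days after discharge -> hospital death, not ICU death
#  4: adult, burns diagnosis -> excluded
#  5: adult, no reason-for-admission record -> excluded
#  6: admitted 2019-06-30 -> outside window
#  7: admitted 2019-07-01 -> inside window
mini_store <- function() {
  person <- tibble::tibble(
    person_id = 1:7,
    gender_concept_id = c(8507L, 8507L, 8532L, 8507L, 8532L, 8507L, 8532L),
    year_of_birth = c(2003L, 2004L, 1960L, 1970L, 1980L, 1955L, 1950L))
  visit_occurrence <- tibble::tibble(
    visit_occurrence_id = 1:7, person_id = 1:7,
    visit_start_date = as.Date(c("2020-01-01", "2020-02-01", "2020-03-01",
                                 "2020-04-01", "2020-05-01", "2019-06-29",
                                 "2019-07-01")),
    visit_end_date = as.Date(c("2020-01-10", "2020-02-10", "2020-03-20",
                               "2020-04-10", "2020-05-10", "2019-07-10",
                               "2019-07-10")))
  visit_detail <- tibble::tibble(
    visit_detail_id = 1:8,
    visit_occurrence_id = c(1:7, 3L),
    person_id = c(1:7, 3L),
    care_site_id = 1L,
    visit_detail_start_datetime = ts(c(
      "2020-01-01 08:00:00", "2020-02-01 08:00:00", "2020-03-01 08:00:00",
      "2020-04-01 08:00:00", "2020-05-01 08:00:00", "2019-06-30 23:00:00",
      "2019-07-01 00:00:00", "2020-03-10 08:00:00")),
    visit_detail_end_datetime = ts(c(
      "2020-01-03 20:00:00", "2020-02-03 08:00:00", "2020-03-05 08:00:00",
      "2020-04-03 08:00:00", "2020-05-03 08:00:00", "2019-07-02 08:00:00",
      "2019-07-03 08:00:00", "2020-03-12 08:00:00")))
  # person 1 leukocyte series under BOTH concept codes (pooled by config):
  # 3.1 at +1h, 9.8 at +23h (in window), 40 at +25h (out of window);
  # plus one temperature with a mismatched unit (dropped with warning)
  measurement <- tibble::tibble(
    measurement_id = 1:6,
    person_id = c(1L, 1L, 1L, 1L, 1L, 7L),
    visit_detail_id = c(1L, 1L, 1L, 1L, 1L, 7L),
    measurement_concept_id = c(3000905L, 3003282L, 3000905L, 3020891L,
                               3020891L, 3027018L),
    measurement_datetime = ts(c(
      "2020-01-01 09:00:00", "2020-01-02 07:00:00", "2020-01-02 09:00:00",
      "2020-01-01 10:00:00", "2020-01-01 11:00:00", "2019-07-01 05:00:00")),
    value_as_number = c(3.1, 9.8, 40, 37.2, 39.0, 82),
    unit_concept_id = c(8961L, 8961L, 8961L, 586323L, 9999L, 8541L))
  reason_vd <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L)
  observation <- tibble::tibble(
    observation_id = seq_along(reason_vd),
    person_id = visit_detail$person_id[match(reason_vd, visit_detail$visit_detail_id)],
    visit_detail_id = reason_vd,
    observation_concept_id = 2000000101L,
    observation_datetime = visit_detail$visit_detail_start_datetime[
      match(reason_vd, visit_detail$visit_detail_id)],
    value_as_number = 414,   # nonop_sepsis in the synthetic intermediate map
    unit_concept_id = NA_integer_)
  condition_occurrence <- tibble::tibble(
    condition_occurrence_id = 1L, person_id = 4L, visit_detail_id = 4L,
    condition_concept_id = 4088927L,
    condition_start_datetime = ts("2020-04-01 09:00:00"))
  death <- tibble::tibble(
    person_id = c(1L, 3L),
    death_datetime = ts(c("2020-01-03 19:00:00", "2020-03-14 08:00:00")))
  omop_store(list(person = person, visit_occurrence = visit_occurrence,
                  visit_detail = visit_detail, measurement = measurement,
                  observation = observation,
                  condition_occurrence = condition_occurrence, death = death),
             source_name = "mini")
}

# dialect-A configuration, with leukocytes accepting both the automated-
# and manual-count concept codes (events under either are pooled)
mini_config <- function() {
  cfg <- dialect_extraction_config("A", source_name = "mini")
  cfg$variables$leukocytes$concept_ids <- c(3000905L, 3003282L)
  cfg
}

# small two-source synthetic study, generated once per test run
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 424242, sources = list(
        sim_source_spec("regA", dialect = "A", n_icus = 3, patients_per_icu = 80,
                        missingness = list(mechanism = "MCAR", rate = 0,
                                           variables = character())),
        sim_source_spec("regB", dialect = "B", n_icus = 3, patients_per_icu = 80,
                        missingness = list(mechanism = "MCAR", rate = 0,
                                           variables = character()))))
      cache <<- generate_store(cfg)
    }
    cache
  }
})

scoring_def <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_scoring_definition()
    cache
  }
})

# one-row wide table for hand-scored patient vignettes
vignette_wide <- function(temperature = NA, map = NA, heart_rate = NA,
                          respiratory_rate = NA, fio2 = NA, pao2 = NA,
                          aado2 = NA, ph = NA, sodium = NA, potassium = NA,
                          creatinine = NA, hematocrit = NA, leukocytes = NA,
                          gcs = NA, arf = FALSE) {
  w <- tibble::tibble(
    temperature_highest = temperature, temperature_lowest = temperature,
    map_highest = map, map_lowest = map,
    heart_rate_highest = heart_rate, heart_rate_lowest = heart_rate,
    respiratory_rate_highest = respiratory_rate,
    respiratory_rate_lowest = respiratory_rate,
    fio2_highest = fio2, pao2_lowest = pao2, aado2_highest = aado2,
    ph_highest = ph, ph_lowest = ph,
    sodium_highest = sodium, sodium_lowest = sodium,
    potassium_highest = potassium, potassium_lowest = potassium,
    creatinine_highest = creatinine, creatinine_lowest = creatinine,
    hematocrit_highest = hematocrit, hematocrit_lowest = hematocrit,
    leukocytes_highest = leukocytes, leukocytes_lowest = leukocytes,
    gcs_lowest = gcs, acute_renal_failure = arf)
  w
}
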