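# Cohort selection and first-24-hour worst-value extraction, driven by a
# per-source configuration that maps each analysis variable to concept
# codes and an OMOP table. The configuration file is the mechanism that
# lets one shared analysis script run against sources whose OMOP builds
# use different base vocabularies (e.g. manual vs automated leukocyte
# count concepts) or different table placement (comorbidities as
# condition_occurrence vs observation).

#' Declare how one analysis variable is stored in a source
#'
#' @param variable_name analysis variable name.
#' @param concept_ids one or more concept codes that identify the variable
#'   in this source; events under any listed code are pooled.
#' @param table OMOP table holding the events.
#' @param aggregation `highest` / `lowest` / `both` for numeric worst-value
#'   extraction, `presence` for flags (comorbidities, admission type).
#' @param unit_concept_id expected unit code; events carrying a different
#'   non-absent unit are dropped with a warning, never converted.
#' @return a `variable_spec` list.
#' @export
variable_spec <- function(variable_name, concept_ids,
                          table = c("measurement", "observation",
                                    "condition_occurrence"),
                          aggregation = c("both", "highest", "lowest", "presence"),
                          unit_concept_id = NA_integer_) {
  table <- match.arg(table)
  aggregation <- match.arg(aggregation)
  if (length(concept_ids) < 1) stopf("variable '%s': empty concept_ids", variable_name)
  if (table == "condition_occurrence" && aggregation != "presence") {
    stopf("variable '%s': condition_occurrence rows carry no numeric value; only aggregation = 'presence' is allowed",
          variable_name)
  }
  structure(list(variable_name = variable_name,
                 concept_ids = as.integer(concept_ids),
                 table = table, aggregation = aggregation,
                 unit_concept_id = as.integer(unit_concept_id)),
            class = "variable_spec")
}

# Numeric variables every config must cover (the APACHE II inputs) and the
# presence flags used for chronic health and admission type.
required_numeric_vars <- function() {
  c("temperature", "map", "heart_rate", "respiratory_rate", "pao2", "aado2",
    "fio2", "ph", "sodium", "potassium", "creatinine", "hematocrit",
    "leukocytes", "gcs")
}
required_presence_vars <- function() {
  c("severe_chronic", "acute_renal_failure", "elective_postop",
    "emergency_postop")
}

#' Assemble a per-source extraction configuration
#'
#' @param source_name data source (quality registry) label.
#' @param variables list of [variable_spec()]s; must cover every APACHE II
#'   component variable exactly once.
#' @param reason list with `concept_ids` and `table` locating the
#'   reason-for-admission record, whose `value_as_number` carries the
#'   source vocabulary code.
#' @param burns_concept_ids condition codes identifying burns diagnoses
#'   (an exclusion criterion).
#' @param gender_male_concept_id concept code for male sex in this source.
#' @param date_window admission window `c(start, end)` (dates, inclusive).
#' @return an `extraction_config` object.
#' @export
extraction_config <- function(source_name, variables, reason,
                              burns_concept_ids, gender_male_concept_id,
                              date_window = as.Date(c("2019-07-01", "2022-12-31"))) {
  nms <- vapply(variables, function(v) v$variable_name, "")
  if (any(duplicated(nms))) {
    stopf("duplicate variable(s) in config: %s",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(variables) <- nms
  missing_vars <- setdiff(c(required_numeric_vars(), required_presence_vars()), nms)
  if (length(missing_vars) > 0) {
    stopf("config '%s' is missing variable(s): %s", source_name,
          paste(missing_vars, collapse = ", "))
  }
  if (is.null(reason$concept_ids) || is.null(reason$table)) {
    abort("config requires a reason-for-admission variable (concept_ids + table)")
  }
  date_window <- as.Date(date_window)
  if (length(date_window) != 2 || date_window[1] >= date_window[2]) {
    abort("date_window must be c(start, end) with start < end")
  }
  structure(list(source_name = source_name, variables = variables,
                 reason = list(concept_ids = as.integer(reason$concept_ids),
                               table = reason$table),
                 burns_concept_ids = as.integer(burns_concept_ids),
                 gender_male_concept_id = as.integer(gender_male_concept_id),
                 date_window = date_window),
            class = "extraction_config")
}

#' Write / read an extraction configuration as YAML
#'
#' @param config an [extraction_config()].
#' @param path file path.
#' @return `read_extraction_config` returns an `extraction_config`.
#' @export
write_extraction_config <- function(config, path) {
  stopifnot(inherits(config, "extraction_config"))
  out <- list(
    source_name = config$source_name,
    date_window = format(config$date_window, "%Y-%m-%d"),
    gender_male_concept_id = config$gender_male_concept_id,
    burns_concept_ids = config$burns_concept_ids,
    reason = list(concept_ids = config$reason$concept_ids,
                  table = config$reason$table),
    variables = lapply(unname(config$variables), function(v) {
      list(variable_name = v$variable_name, concept_ids = v$concept_ids,
           table = v$table, aggregation = v$aggregation,
           unit_concept_id = if (is.na(v$unit_concept_id)) NULL else v$unit_concept_id)
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_extraction_config
#' @export
read_extraction_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vars <- lapply(raw$variables, function(v) {
    variable_spec(v$variable_name, unlist(v$concept_ids), v$table,
                  v$aggregation, v$unit_concept_id %||% NA_integer_)
  })
  extraction_config(raw$source_name, vars, raw$reason,
                    unlist(raw$burns_concept_ids),
                    raw$gender_male_concept_id,
                    as.Date(unlist(raw$date_window)))
}

# Shared synthetic-vocabulary constants: concept and unit codes used by the
# built-in dialects and the data generator. Dialects differ where the two
# registries' OMOP builds differ: the leukocyte concept (automated vs
# manual count) and the table placement of comorbidity flags.
dialect_concepts <- function(dialect = c("A", "B")) {
  dialect <- match.arg(dialect)
  concepts <- list(
    temperature = 3020891L, map = 3027598L, heart_rate = 3027018L,
    respiratory_rate = 3024171L, pao2 = 3027801L, aado2 = 3005424L,
    fio2 = 3020716L, ph = 3010421L, sodium = 3019550L, potassium = 3023103L,
    creatinine = 3016723L, hematocrit = 3023314L,
    leukocytes = if (dialect == "A") 3000905L else 3003282L,
    gcs = 3032652L,
    severe_chronic = 4064161L, acute_renal_failure = 197320L,
    elective_postop = 2000000401L, emergency_postop = 2000000402L,
    reason = if (dialect == "A") 2000000101L else 2000000201L,
    burns = 4088927L
  )
  units <- list(
    temperature = 586323L, map = 8876L, heart_rate = 8541L,
    respiratory_rate = 8541L, pao2 = 8876L, aado2 = 8876L, fio2 = 8523L,
    ph = NA_integer_, sodium = 8753L, potassium = 8753L, creatinine = 8840L,
    hematocrit = 8554L, leukocytes = 8961L, gcs = NA_integer_
  )
  list(dialect = dialect, concepts = concepts, units = units,
       comorbidity_table = if (dialect == "A") "condition_occurrence" else "observation",
       schema_version = if (dialect == "A") "5.3" else "5.4")
}

#' Built-in extraction configuration for a synthetic dialect
#'
#' Dialect `"A"` mirrors a registry that codes leukocytes with the
#' automated-count concept and stores comorbidities as conditions (CDM
#' v5.3 column dialect); dialect `"B"` uses the manual-count concept and
#' stores comorbidities as observations (v5.4). Extraction from either
#' dialect's store with its own configuration yields identical output.
#'
#' @param dialect `"A"` or `"B"`.
#' @param source_name source label; defaults to `source_<dialect>`.
#' @param date_window admission window.
#' @return an [extraction_config()].
#' @export
dialect_extraction_config <- function(dialect = c("A", "B"),
                                      source_name = NULL,
                                      date_window = as.Date(c("2019-07-01", "2022-12-31"))) {
  dialect <- match.arg(dialect)
  d <- dialect_concepts(dialect)
  source_name <- source_name %||% paste0("source_", dialect)
  num <- lapply(required_numeric_vars(), function(v) {
    agg <- switch(v, pao2 = "lowest", aado2 = "highest", fio2 = "highest",
                  gcs = "lowest", "both")
    variable_spec(v, d$concepts[[v]], "measurement", agg, d$units[[v]])
  })
  pres <- lapply(required_presence_vars(), function(v) {
    tab <- if (v %in% c("severe_chronic", "acute_renal_failure")) {
      d$comorbidity_table
    } else {
      "observation"
    }
    variable_spec(v, d$concepts[[v]], tab, "presence")
  })
  extraction_config(
    source_name = source_name,
    variables = c(num, pres),
    reason = list(concept_ids = d$concepts$reason, table = "observation"),
    burns_concept_ids = d$concepts$burns,
    gender_male_concept_id = 8507L,
    date_window = date_window
  )
}

# Pull the events of one table restricted to a concept set and, optionally,
# to the expected unit. Mismatched non-absent units are dropped with a
# warning: silent unit conversion is a known source of cross-registry error.
events_for <- function(store, table, concept_ids, unit_concept_id = NA,
                       variable = "") {
  df <- store[[table]]
  id_col <- switch(table, measurement = "measurement_concept_id",
                   observation = "observation_concept_id",
                   condition_occurrence = "condition_concept_id")
  ts_col <- switch(table, measurement = "measurement_datetime",
                   observation = "observation_datetime",
                   condition_occurrence = "condition_start_datetime")
  df <- df[df[[id_col]] %in% concept_ids, , drop = FALSE]
  df$event_datetime <- df[[ts_col]]
  if (!is.na(unit_concept_id) && "unit_concept_id" %in% names(df)) {
    bad <- !is.na(df$unit_concept_id) & df$unit_concept_id != unit_concept_id
    if (any(bad)) {
      warn(sprintf("variable '%s': dropping %d event(s) with unexpected unit_concept_id",
                   variable, sum(bad)))
      df <- df[!bad, , drop = FALSE]
    }
  }
  df
}

#' Select the analysis cohort and report attrition
#'
#' Applies the inclusion/exclusion rules in a fixed order — admission
#' inside the date window, age >= 17 years, no burns diagnosis, a recorded
#' reason for admission, first ICU stay per hospital visit — and counts
#' each step. Age at admission is admission year minus year of birth (the
#' person table stores year only); an age of exactly 17 is eligible.
#'
#' @param store an [omop_store()].
#' @param config an [extraction_config()].
#' @return list with `cohort` (one row per retained ICU admission) and
#'   `attrition` (step, excluded, remaining).
#' @export
select_cohort <- function(store, config) {
  stopifnot(inherits(store, "omop_store"), inherits(config, "extraction_config"))
  vd <- store$visit_detail
  vo <- store$visit_occurrence
  per <- store$person
  rows <- vd |>
    dplyr::inner_join(per, by = "person_id") |>
    dplyr::inner_join(vo[, c("visit_occurrence_id", "person_id")],
                      by = c("visit_occurrence_id", "person_id")) |>
    dplyr::transmute(
      person_id = .data$person_id,
      visit_occurrence_id = .data$visit_occurrence_id,
      visit_detail_id = .data$visit_detail_id,
      icu_id = .data$care_site_id,
      icu_admit = .data$visit_detail_start_datetime,
      icu_discharge = .data$visit_detail_end_datetime,
      age = as.integer(format(.data$icu_admit, "%Y", tz = "UTC")) -
        .data$year_of_birth,
      sex = ifelse(.data$gender_concept_id == config$gender_male_concept_id,
                   "male", "female"))

  steps <- list()
  note <- function(label, kept) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = label, excluded = nrow(rows) - nrow(kept), remaining = nrow(kept))
    kept
  }
  steps[[1]] <- tibble::tibble(step = "icu_admissions", excluded = 0L,
                               remaining = nrow(rows))

  admit_date <- as.Date(rows$icu_admit, tz = "UTC")
  rows <- note("outside_date_window",
               rows[admit_date >= config$date_window[1] &
                    admit_date <= config$date_window[2], ])
  rows <- note("age_under_17", rows[rows$age >= 17, ])

  burns <- events_for(store, "condition_occurrence", config$burns_concept_ids)
  rows <- note("burns_diagnosis",
               rows[!rows$visit_detail_id %in% burns$visit_detail_id, ])

  reason_events <- events_for(store, config$reason$table,
                              config$reason$concept_ids) |>
    dplyr::filter(!is.na(.data$value_as_number), !is.na(.data$visit_detail_id)) |>
    dplyr::arrange(.data$event_datetime) |>
    dplyr::distinct(.data$visit_detail_id, .keep_all = TRUE) |>
    dplyr::transmute(visit_detail_id = .data$visit_detail_id,
                     reason_code = as.integer(.data$value_as_number))
  rows <- dplyr::left_join(rows, reason_events, by = "visit_detail_id")
  rows <- note("missing_reason_for_admission", rows[!is.na(rows$reason_code), ])

  first_stays <- rows |>
    dplyr::arrange(.data$visit_occurrence_id, .data$icu_admit,
                   .data$visit_detail_id) |>
    dplyr::distinct(.data$visit_occurrence_id, .keep_all = TRUE)
  rows <- note("icu_readmission_within_visit", first_stays)

  for (v in c("elective_postop", "emergency_postop")) {
    sp <- config$variables[[v]]
    ev <- events_for(store, sp$table, sp$concept_ids)
    rows[[v]] <- rows$visit_detail_id %in% ev$visit_detail_id
  }
  list(cohort = rows, attrition = dplyr::bind_rows(steps))
}

#' Extract first-24-hour worst values per admission
#'
#' For each configured variable, scans only events whose concept code,
#' table, and visit linkage match and whose timestamp lies in the
#' half-open window `[icu_admit, icu_admit + 24h)`, then takes the
#' maximum/minimum of `value_as_number` per admission. Absent when no
#' qualifying event exists. Presence variables yield `TRUE` when any
#' linked event exists (window-free: a comorbidity is an admission
#' attribute, not a timed sample) and `FALSE` otherwise.
#'
#' @param store an [omop_store()].
#' @param cohort cohort table from [select_cohort()].
#' @param config an [extraction_config()].
#' @return wide tibble, one row per admission: `<var>_highest` /
#'   `<var>_lowest` numeric columns and logical presence columns.
#' @export
extract_first24h <- function(store, cohort, config) {
  window <- cohort[, c("visit_detail_id", "icu_admit")]
  wide <- cohort[, c("visit_detail_id",
                     intersect(c("person_id", "icu_id"), names(cohort)))]
  for (sp in config$variables) {
    ev <- events_for(store, sp$table, sp$concept_ids, sp$unit_concept_id,
                     sp$variable_name)
    if (sp$aggregation == "presence") {
      wide[[sp$variable_name]] <-
        wide$visit_detail_id %in% ev$visit_detail_id[!is.na(ev$visit_detail_id)]
      next
    }
    ev <- ev |>
      dplyr::inner_join(window, by = "visit_detail_id") |>
      dplyr::filter(!is.na(.data$value_as_number),
                    .data$event_datetime >= .data$icu_admit,
                    .data$event_datetime < .data$icu_admit + 24 * 3600)
    agg <- if (nrow(ev) == 0) {
      tibble::tibble(visit_detail_id = integer(), highest = double(),
                     lowest = double())
    } else {
      ev |>
        dplyr::group_by(.data$visit_detail_id) |>
        dplyr::summarise(highest = max(.data$value_as_number),
                         lowest = min(.data$value_as_number), .groups = "drop")
    }
    hit <- match(wide$visit_detail_id, agg$visit_detail_id)
    if (sp$aggregation %in% c("highest", "both")) {
      wide[[paste0(sp$variable_name, "_highest")]] <- agg$highest[hit]
    }
    if (sp$aggregation %in% c("lowest", "both")) {
      wide[[paste0(sp$variable_name, "_lowest")]] <- agg$lowest[hit]
    }
  }
  tibble::as_tibble(wide)
}

#' Attach the ICU outcome to a cohort
#'
#' ICU death is a death record whose timestamp falls inside the ICU stay,
#' `[icu_admit, icu_discharge]` closed; a death after ICU discharge is a
#' hospital death and does not count. Length of stay is in fractional
#' days. A death timestamped before admission is a data fault: the row is
#' flagged (`death_before_admission`) and a warning raised.
#'
#' @param store an [omop_store()].
#' @param cohort cohort table from [select_cohort()].
#' @return cohort with `icu_death`, `icu_los_days`,
#'   `death_before_admission` columns.
#' @export
attach_outcome <- function(store, cohort) {
  dd <- store$death
  hit <- match(cohort$person_id, dd$person_id)
  death_dt <- dd$death_datetime[hit]
  has_end <- !is.na(cohort$icu_discharge)
  cohort$icu_death <- !is.na(death_dt) & death_dt >= cohort$icu_admit &
    (!has_end | death_dt <= cohort$icu_discharge)
  cohort$icu_los_days <- as.numeric(difftime(cohort$icu_discharge,
                                             cohort$icu_admit, units = "days"))
  cohort$death_before_admission <- !is.na(death_dt) & death_dt < cohort$icu_admit
  if (any(cohort$death_before_admission)) {
    warn(sprintf("%d admission(s) have a death record before ICU admission; rows flagged",
                 sum(cohort$death_before_admission)))
  }
  cohort
}
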