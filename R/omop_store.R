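# OMOP CDM table subset: load, validate, write.
#
# The store holds the seven tables both registries populated for this
# analysis (person, visit_occurrence, visit_detail, measurement,
# observation, condition_occurrence, death). Other CDM tables present on
# disk (procedure_occurrence, observation_period, care_site, drug_exposure,
# ...) are loaded verbatim and carried along but ignored downstream: the
# severity model does not use them.
#
# Conventions: visit_occurrence carries dates; visit_detail and clinical
# events carry ISO-8601 timestamps (UTC); an empty field is absent (NA).

# Canonical column layout per table. type: i = integer, d = double,
# D = date, T = timestamp. required = FALSE means NA-able / omittable.
omop_schema <- function() {
  list(
    person = list(
      cols = c(person_id = "i", gender_concept_id = "i", year_of_birth = "i"),
      required = c("person_id", "gender_concept_id", "year_of_birth")
    ),
    visit_occurrence = list(
      cols = c(visit_occurrence_id = "i", person_id = "i",
               visit_start_date = "D", visit_end_date = "D",
               discharged_to_concept_id = "i"),
      required = c("visit_occurrence_id", "person_id", "visit_start_date")
    ),
    visit_detail = list(
      cols = c(visit_detail_id = "i", visit_occurrence_id = "i",
               person_id = "i", care_site_id = "i",
               visit_detail_start_datetime = "T",
               visit_detail_end_datetime = "T",
               discharged_to_concept_id = "i"),
      required = c("visit_detail_id", "visit_occurrence_id", "person_id",
                   "visit_detail_start_datetime")
    ),
    measurement = list(
      cols = c(measurement_id = "i", person_id = "i", visit_detail_id = "i",
               measurement_concept_id = "i", measurement_datetime = "T",
               value_as_number = "d", unit_concept_id = "i"),
      required = c("measurement_id", "person_id", "measurement_concept_id",
                   "measurement_datetime")
    ),
    observation = list(
      cols = c(observation_id = "i", person_id = "i", visit_detail_id = "i",
               observation_concept_id = "i", observation_datetime = "T",
               value_as_number = "d", unit_concept_id = "i"),
      required = c("observation_id", "person_id", "observation_concept_id",
                   "observation_datetime")
    ),
    condition_occurrence = list(
      cols = c(condition_occurrence_id = "i", person_id = "i",
               visit_detail_id = "i", condition_concept_id = "i",
               condition_start_datetime = "T"),
      required = c("condition_occurrence_id", "person_id",
                   "condition_concept_id", "condition_start_datetime")
    ),
    death = list(
      cols = c(person_id = "i", death_datetime = "T"),
      required = c("person_id", "death_datetime")
    )
  )
}

core_tables <- function() names(omop_schema())

# CDM v5.3 column names that v5.4 renamed. Neither spelling is used by the
# downstream analysis; the loader just normalizes to the v5.4 name so that
# stores loaded from either version compare equal field-for-field.
dialect_synonyms <- list(
  visit_occurrence = c(discharge_to_concept_id = "discharged_to_concept_id"),
  visit_detail     = c(discharge_to_concept_id = "discharged_to_concept_id")
)

#' Construct an OMOP store from in-memory tables
#'
#' @param tables named list of data frames; must include the seven core
#'   tables (`person`, `visit_occurrence`, `visit_detail`, `measurement`,
#'   `observation`, `condition_occurrence`, `death`). Extra tables are kept
#'   but ignored by the analysis stages.
#' @param schema_version `"5.3"` or `"5.4"` (column-name dialect only).
#' @param source_name label for the data source (quality registry).
#' @return an `omop_store` object (list of tibbles with attributes).
#' @export
omop_store <- function(tables, schema_version = "5.4", source_name = "source") {
  schema_version <- match.arg(as.character(schema_version), c("5.3", "5.4"))
  missing_tabs <- setdiff(core_tables(), names(tables))
  if (length(missing_tabs) > 0) {
    stopf("missing required OMOP tables: %s",
          paste(missing_tabs, collapse = ", "))
  }
  sch <- omop_schema()
  out <- lapply(names(tables), function(tab) {
    df <- tibble::as_tibble(tables[[tab]])
    if (!tab %in% names(sch)) return(df)
    df <- normalize_columns(df, tab)
    coerce_table(df, tab)
  })
  names(out) <- names(tables)
  structure(out, class = "omop_store",
            schema_version = "5.4", source_name = source_name)
}

#' @export
print.omop_store <- function(x, ...) {
  cat(sprintf("<omop_store> source '%s' (CDM column dialect normalized)\n",
              attr(x, "source_name")))
  for (tab in names(x)) cat(sprintf("  %-22s %8d rows\n", tab, nrow(x[[tab]])))
  invisible(x)
}

normalize_columns <- function(df, tab) {
  syn <- dialect_synonyms[[tab]]
  if (!is.null(syn)) {
    hits <- intersect(names(syn), names(df))
    for (old in hits) {
      if (!syn[[old]] %in% names(df)) names(df)[names(df) == old] <- syn[[old]]
    }
  }
  df
}

# Coerce character/raw input columns to canonical types; report unparseable
# dates with their row indices rather than silently dropping them.
coerce_table <- function(df, tab) {
  spec <- omop_schema()[[tab]]
  miss <- setdiff(spec$required, names(df))
  if (length(miss) > 0) {
    stopf("table '%s' is missing required columns: %s",
          tab, paste(miss, collapse = ", "))
  }
  for (col in names(spec$cols)) {
    ty <- spec$cols[[col]]
    if (!col %in% names(df)) {
      df[[col]] <- switch(ty,
        i = NA_integer_, d = NA_real_,
        D = as.Date(NA), T = as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"))
      next
    }
    x <- df[[col]]
    if (is.character(x)) x[!nzchar(trimws(x))] <- NA
    parsed <- switch(ty,
      i = suppressWarnings(as.integer(x)),
      d = suppressWarnings(as.double(x)),
      D = if (inherits(x, "Date")) x else as.Date(suppressWarnings(parse_ts(x))),
      T = if (inherits(x, "POSIXct")) {
        attr(x, "tzone") <- "UTC"
        x
      } else {
        suppressWarnings(parse_ts(x))
      })
    bad <- which(is.na(parsed) & !is.na(x))
    if (length(bad) > 0) {
      stopf("table '%s', column '%s': unparseable values at rows %s",
            tab, col, paste(head(bad, 10), collapse = ", "))
    }
    df[[col]] <- parsed
  }
  df[, names(spec$cols)]
}

#' Load an OMOP store from a directory of delimited tables
#'
#' Expects one `<table>.csv` per table (header row, ISO-8601 dates and
#' timestamps, empty string for absent values). Column-name differences
#' between CDM v5.3 and v5.4 are limited to renamed columns not used by the
#' analysis and are normalized on load, so the two versions load to
#' identical internal stores.
#'
#' @param path directory containing the table files.
#' @param schema_version `"5.3"` or `"5.4"`.
#' @param source_name data source label; defaults to the directory name.
#' @return an [omop_store()] object.
#' @export
load_store <- function(path, schema_version = "5.4",
                       source_name = basename(path)) {
  if (!dir.exists(path)) stopf("store directory does not exist: %s", path)
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  tabs <- sub("\\.csv$", "", basename(files))
  missing_tabs <- setdiff(core_tables(), tabs)
  if (length(missing_tabs) > 0) {
    stopf("missing required table files in %s: %s", path,
          paste(paste0(missing_tabs, ".csv"), collapse = ", "))
  }
  tables <- lapply(files, function(f) {
    readr::read_csv(f, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, na = character())
  })
  names(tables) <- tabs
  omop_store(tables, schema_version = schema_version, source_name = source_name)
}

#' Write an OMOP store to a directory of delimited tables
#'
#' One CSV per table; absent values are written as empty strings, never
#' coerced to zero. `load_store(write_store(s))` reproduces `s`
#' field-for-field.
#'
#' @param store an [omop_store()] object.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "omop_store"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stopf("cannot create store directory: %s", path)
  sch <- omop_schema()
  for (tab in names(store)) {
    df <- store[[tab]]
    if (tab %in% names(sch)) {
      for (col in names(df)) {
        if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_ts(df[[col]])
        if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
      }
    }
    readr::write_csv(df, file.path(path, paste0(tab, ".csv")), na = "")
  }
  invisible(path)
}

#' Validate referential integrity and typed invariants of a store
#'
#' Violations are returned as data, one row each, never raised as errors:
#' an empty result means the store is valid.
#'
#' @param store an [omop_store()] object.
#' @return tibble with columns `table`, `row`, `rule`, `detail`.
#' @export
validate_store <- function(store) {
  stopifnot(inherits(store, "omop_store"))
  v <- list()
  add <- function(tab, rows, rule, detail) {
    if (length(rows) == 0) return()
    v[[length(v) + 1]] <<- tibble::tibble(
      table = tab, row = as.integer(rows), rule = rule, detail = detail)
  }
  per <- store$person
  dup <- which(duplicated(per$person_id))
  add("person", dup, "person_id_unique", "duplicated person_id")
  bad_yob <- which(!is.na(per$year_of_birth) &
                   (per$year_of_birth < 1900 |
                    per$year_of_birth > as.integer(format(Sys.Date(), "%Y"))))
  add("person", bad_yob, "year_of_birth_range", "year_of_birth outside [1900, current year]")

  pid <- per$person_id
  vo <- store$visit_occurrence
  add("visit_occurrence", which(!vo$person_id %in% pid),
      "fk_person", "person_id not in person")
  add("visit_occurrence",
      which(!is.na(vo$visit_end_date) & vo$visit_end_date < vo$visit_start_date),
      "date_order", "visit_end_date before visit_start_date")

  vd <- store$visit_detail
  add("visit_detail", which(!vd$person_id %in% pid), "fk_person",
      "person_id not in person")
  add("visit_detail", which(!vd$visit_occurrence_id %in% vo$visit_occurrence_id),
      "fk_visit_occurrence", "visit_occurrence_id not in visit_occurrence")
  add("visit_detail",
      which(!is.na(vd$visit_detail_end_datetime) &
            vd$visit_detail_end_datetime < vd$visit_detail_start_datetime),
      "time_order", "visit_detail end before start")

  vdid <- vd$visit_detail_id
  for (tab in c("measurement", "observation", "condition_occurrence")) {
    df <- store[[tab]]
    add(tab, which(!df$person_id %in% pid), "fk_person", "person_id not in person")
    add(tab, which(!is.na(df$visit_detail_id) & !df$visit_detail_id %in% vdid),
        "fk_visit_detail", "visit_detail_id not in visit_detail")
  }
  add("measurement", which(is.na(store$measurement$value_as_number)),
      "measurement_value_present", "measurement row without value_as_number")

  de <- store$death
  add("death", which(!de$person_id %in% pid), "fk_person", "person_id not in person")
  add("death", which(duplicated(de$person_id)), "death_unique",
      "more than one death record for person")

  if (length(v) == 0) {
    tibble::tibble(table = character(), row = integer(),
                   rule = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}
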