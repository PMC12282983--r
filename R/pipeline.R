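# End-to-end orchestration: extract -> score -> (impute) -> benchmark ->
# report, run identically against every configured source — the federated
# contract is one shared script plus per-source configuration. Only
# registry-level aggregates leave a source's run directory; person-level
# intermediates stay inside it.

#' Score a cohort: APACHE II totals and predicted risks
#'
#' Maps reason-for-admission codes to diagnostic categories, resolves
#' missing components with the source's strategy, and computes total
#' scores and mortality risks. Under multiple imputation the per-patient
#' risk is the mean of the per-imputation risks; per-imputation scored
#' tables are returned for Rubin-pooled registry inference.
#'
#' @param cohort cohort with outcomes (see [select_cohort()],
#'   [attach_outcome()]); must carry `reason_code`, `elective_postop`,
#'   `emergency_postop`, `age`, `icu_death`, `icu_los_days`.
#' @param wide wide table from [extract_first24h()] (carries the
#'   component extrema plus `severe_chronic` / `acute_renal_failure`
#'   presence flags).
#' @param definition an [load_scoring_definition()].
#' @param map a [diagnosis_map()] for this source's reason vocabulary.
#' @param strategy `"normal_fill"` or `"mi_pmm"`.
#' @param mi an [mi_config()] (used by `mi_pmm`).
#' @param source_name registry label attached to the scored rows.
#' @param use_bicarbonate_fallback passed to the component scorer.
#' @return list with `scored` (one row per admission: ids, demographics,
#'   outcome, `aps`, `total`, `risk`), `per_imputation` (list of scored
#'   tables, `NULL` under normal fill), `unmapped_codes`, `strategy`.
#' @export
score_admissions <- function(cohort, wide, definition, map,
                             strategy = c("normal_fill", "mi_pmm"),
                             mi = mi_config(), source_name = "source",
                             use_bicarbonate_fallback = FALSE) {
  strategy <- match.arg(strategy)
  mr <- map_reason(cohort$reason_code, map, definition)
  unmapped <- unique(cohort$reason_code[is.na(mr$category)])
  if (length(unmapped) > 0) {
    warn(sprintf("%d admission(s) with reason codes the map does not cover were excluded: %s",
                 sum(is.na(mr$category)),
                 paste(head(unmapped, 5), collapse = ", ")))
  }
  keep <- !is.na(mr$category)
  cohort <- cohort[keep, ]
  mr <- mr[keep, ]
  wide <- wide[match(cohort$visit_detail_id, wide$visit_detail_id), ]

  base <- tibble::tibble(
    source = source_name,
    person_id = cohort$person_id,
    visit_detail_id = cohort$visit_detail_id,
    icu_id = cohort$icu_id,
    age = cohort$age, sex = cohort$sex,
    category = mr$category,
    icu_death = cohort$icu_death,
    icu_los_days = cohort$icu_los_days)

  score_one <- function(w) {
    pts <- score_components(w, definition, use_bicarbonate_fallback)
    totals <- compute_total(pts, cohort$age, w$severe_chronic, mr$operative,
                            cohort$elective_postop, definition)
    risk <- mortality_risk(totals$total, mr$weight, cohort$emergency_postop,
                           definition)
    dplyr::bind_cols(base, totals, tibble::tibble(risk = risk))
  }

  if (strategy == "normal_fill") {
    pts <- normal_fill(wide, definition, use_bicarbonate_fallback)
    totals <- compute_total(pts, cohort$age, wide$severe_chronic,
                            mr$operative, cohort$elective_postop, definition)
    risk <- mortality_risk(totals$total, mr$weight, cohort$emergency_postop,
                           definition)
    scored <- dplyr::bind_cols(base, totals, tibble::tibble(risk = risk))
    return(list(scored = scored, per_imputation = NULL,
                unmapped_codes = unmapped, strategy = strategy))
  }

  mi_input <- dplyr::bind_cols(
    wide,
    tibble::tibble(icu_death = cohort$icu_death,
                   icu_los_days = cohort$icu_los_days))
  imp <- mi_pmm(mi_input, mi)
  per_imp <- lapply(imp$completed, score_one)
  risk_mat <- vapply(per_imp, function(s) s$risk, numeric(nrow(base)))
  total_mat <- vapply(per_imp, function(s) as.numeric(s$total), numeric(nrow(base)))
  scored <- dplyr::bind_cols(base, tibble::tibble(
    aps = NA_integer_,
    total = rowMeans(total_mat),
    risk = rowMeans(risk_mat)))
  list(scored = scored, per_imputation = per_imp, unmapped_codes = unmapped,
       strategy = strategy, imputation = imp)
}

#' Assemble a pipeline run configuration
#'
#' @param sources list of per-source entries; each a list with `name`,
#'   either `store` (an [omop_store()]) or `store_path`, either `config`
#'   (an [extraction_config()]) or `config_path` or `dialect`
#'   (`"A"`/`"B"` for the built-in configs and synthetic diagnosis maps),
#'   optionally `map` / `map_path` / `map_via_path`, and `strategy`
#'   (`"normal_fill"` or `"mi_pmm"`).
#' @param out_dir run directory to create.
#' @param level benchmark aggregation level.
#' @param mi an [mi_config()] shared by `mi_pmm` sources.
#' @param seed run seed (feeds the imputation sub-seeds).
#' @param funnel_format `"svg"` or `"png"`.
#' @return a `run_config` list.
#' @export
run_config <- function(sources, out_dir, level = c("registry", "icu"),
                       mi = mi_config(), seed = 1, funnel_format = "svg") {
  level <- match.arg(level)
  for (s in sources) {
    if (is.null(s$name)) abort("every source needs a name")
    if (is.null(s$strategy) ||
        !s$strategy %in% c("normal_fill", "mi_pmm")) {
      stopf("source '%s': strategy must be 'normal_fill' or 'mi_pmm'", s$name)
    }
    if (is.null(s$store) && is.null(s$store_path)) {
      stopf("source '%s': needs store or store_path", s$name)
    }
    if (!is.null(s$store_path) && !dir.exists(s$store_path)) {
      stopf("source '%s': store_path does not exist", s$name)
    }
    for (p in c("config_path", "map_path", "map_via_path")) {
      if (!is.null(s[[p]]) && !file.exists(s[[p]])) {
        stopf("source '%s': %s does not exist", s$name, p)
      }
    }
  }
  structure(list(sources = sources, out_dir = out_dir, level = level,
                 mi = mi, seed = as.integer(seed),
                 funnel_format = funnel_format),
            class = "run_config")
}

#' Run the full benchmarking pipeline
#'
#' For each source: load and validate the store, select the cohort and
#' attach outcomes, extract first-24h worst values, score with the
#' source's missingness strategy, and write per-source artifacts
#' (attrition report, wide table, scores, demographics) into
#' `<out_dir>/<source>/`. Registry-level aggregates (unit statistics,
#' funnel plot, outlier table) and a provenance manifest are written at
#' the top level; no person-level rows cross the source boundary. A rerun
#' with the same configuration reproduces the outputs.
#'
#' @param cfg a [run_config()].
#' @return the run directory path, invisibly; aggregate statistics as
#'   attribute `"registry_stats"`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  definition <- load_scoring_definition()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_counts <- list()
  agg <- list()
  pooled_any <- FALSE
  seeds <- child_seeds(cfg$seed, length(cfg$sources))

  for (si in seq_along(cfg$sources)) {
    s <- cfg$sources[[si]]
    src_dir <- file.path(cfg$out_dir, s$name)
    dir.create(src_dir, recursive = TRUE, showWarnings = FALSE)
    store <- s$store %||% load_store(s$store_path, source_name = s$name)
    viol <- validate_store(store)
    if (nrow(viol) > 0) {
      readr::write_csv(viol, file.path(src_dir, "validation_violations.csv"))
      stopf("source '%s': store failed validation (%d violation(s); see %s)",
            s$name, nrow(viol), file.path(src_dir, "validation_violations.csv"))
    }
    config <- s$config %||%
      (if (!is.null(s$config_path)) read_extraction_config(s$config_path)
       else dialect_extraction_config(s$dialect, source_name = s$name))
    map <- s$map %||%
      (if (!is.null(s$map_path)) read_diagnosis_map(s$map_path, s$map_via_path)
       else dialect_diagnosis_map(s$dialect))

    sel <- select_cohort(store, config)
    cohort <- attach_outcome(store, sel$cohort)
    wide <- extract_first24h(store, cohort, config)
    mi <- cfg$mi
    mi$seed <- seeds[si]
    res <- score_admissions(cohort, wide, definition, map,
                            strategy = s$strategy, mi = mi,
                            source_name = s$name)

    readr::write_csv(sel$attrition, file.path(src_dir, "attrition.csv"))
    readr::write_csv(wide, file.path(src_dir, "wide.csv"))
    readr::write_csv(res$scored, file.path(src_dir, "scores.csv"))
    readr::write_csv(demographics_table(res$scored),
                     file.path(src_dir, "demographics.csv"))

    stage_counts[[s$name]] <- list(
      store_rows = lapply(store, nrow)[core_tables()],
      cohort = nrow(cohort), scored = nrow(res$scored))
    if (s$strategy == "mi_pmm") {
      pooled_any <- TRUE
      agg[[s$name]] <- pooled_funnel(res$per_imputation, cfg$level)$stats
    } else {
      one <- compute_smr(res$scored, cfg$level)
      one$expected_lo95 <- one$expected
      one$expected_hi95 <- one$expected
      one$smr_lo95 <- one$smr
      one$smr_hi95 <- one$smr
      one$between_var <- NA_real_
      one$mi_degenerate <- NA
      agg[[s$name]] <- one
    }
  }

  stats <- dplyr::bind_rows(agg)
  stats_out <- if (pooled_any) stats else
    stats[, setdiff(names(stats), c("expected_lo95", "expected_hi95",
                                    "smr_lo95", "smr_hi95", "between_var",
                                    "mi_degenerate"))]
  readr::write_csv(stats_out, file.path(cfg$out_dir, "registry_stats.csv"))
  outlier_cols <- intersect(c("source", "icu_id", "n_admissions", "observed",
                              "expected", "smr"), names(stats))
  readr::write_csv(funnel_outliers(stats[, outlier_cols]),
                   file.path(cfg$out_dir, "funnel_outliers.csv"))
  plot_funnel(stats, path = file.path(cfg$out_dir,
                                      paste0("funnel.", cfg$funnel_format)))

  manifest <- list(
    package = "icubench",
    package_version = as.character(utils::packageVersion("icubench")),
    seed = cfg$seed,
    level = cfg$level,
    config_hash = rlang::hash(cfg),
    sources = stage_counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out <- invisible(cfg$out_dir)
  attr(out, "registry_stats") <- stats
  out
}
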