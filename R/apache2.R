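# APACHE II severity scoring: component points from worst first-24h values,
# acute physiology score, total score, and predicted ICU mortality risk.
#
# The scoring tables and logistic constants live in a packaged,
# human-auditable YAML file (inst/extdata/apache2_scoring.yaml) rather than
# in code, so the transcription of the published model can be audited and
# swapped. Band semantics: inclusive [lo, hi] ranges; a value falling in a
# printed gap between adjacent bands takes the adjacent band with the
# higher point value (edge cases resolve toward severity).

# Plausibility domain per variable; values outside are treated as data
# errors, not extreme physiology.
apache2_domains <- function() {
  list(
    temperature = c(25, 46), map = c(10, 300), heart_rate = c(0, 350),
    respiratory_rate = c(0, 120), pao2 = c(10, 800), aado2 = c(0, 900),
    ph = c(6.5, 8), sodium = c(80, 220), potassium = c(0.5, 12),
    creatinine = c(0, 30), hematocrit = c(5, 80), leukocytes = c(0, 300),
    gcs = c(3, 15), bicarbonate = c(1, 80)
  )
}

# The 12 physiologic components in scoring order.
apache2_components <- function() {
  c("temperature", "map", "heart_rate", "respiratory_rate", "oxygenation",
    "ph", "sodium", "potassium", "creatinine", "hematocrit", "leukocytes",
    "gcs")
}

#' Load and validate an APACHE II scoring definition
#'
#' @param path YAML definition file; defaults to the definition shipped
#'   with the package.
#' @return an `apache2_definition` object: physiology band tables, age
#'   bands, chronic-health points, diagnostic-category weights, and the
#'   mortality logistic constants.
#' @export
load_scoring_definition <- function(path = NULL) {
  path <- path %||% system.file("extdata", "apache2_scoring.yaml",
                                package = "icubench")
  raw <- yaml::read_yaml(path)
  band_tbl <- function(bands) {
    tibble::tibble(
      lo = vapply(bands, function(b) b$lo %||% -Inf, 1.0),
      hi = vapply(bands, function(b) b$hi %||% Inf, 1.0),
      points = vapply(bands, function(b) as.integer(b$points), 1L)
    ) |> dplyr::arrange(.data$lo)
  }
  def <- list(
    physiology = lapply(raw$physiology, function(v) band_tbl(v$bands)),
    age = band_tbl(raw$age_points),
    chronic = list(
      elective_postoperative = raw$chronic_health$elective_postoperative,
      nonoperative_or_emergency_postoperative =
        raw$chronic_health$nonoperative_or_emergency_postoperative
    ),
    logistic = raw$logistic,
    categories = tibble::tibble(
      category = vapply(raw$diagnostic_categories, function(x) x$name, ""),
      weight = vapply(raw$diagnostic_categories, function(x) x$weight, 1.0),
      operative = vapply(raw$diagnostic_categories, function(x) x$operative, TRUE)
    )
  )
  class(def) <- "apache2_definition"
  validate_scoring_definition(def)
  def
}

#' Validate an APACHE II scoring definition
#'
#' Rejects overlapping or unordered band tables, band tables without a
#' single normal (0-point) band, and point values that do not increase
#' away from normal. Run automatically by [load_scoring_definition()].
#'
#' @param def an `apache2_definition` object.
#' @return `def`, invisibly; errors on the first violation.
#' @export
validate_scoring_definition <- function(def) {
  for (var in names(def$physiology)) {
    b <- def$physiology[[var]]
    if (any(b$lo[-1] <= b$hi[-nrow(b)])) {
      stopf("scoring definition '%s': overlapping or unordered bands", var)
    }
    zero <- which(b$points == 0)
    if (var %in% c("aado2")) {
      # one-sided: points weakly increase upward
      if (any(diff(b$points) < 0)) {
        stopf("scoring definition '%s': points not monotone", var)
      }
    } else if (length(zero) != 1) {
      stopf("scoring definition '%s': needs exactly one normal (0) band", var)
    } else {
      below <- b$points[seq_len(zero)]
      above <- b$points[zero:nrow(b)]
      if (any(diff(below) > 0) || any(diff(above) < 0)) {
        stopf("scoring definition '%s': points must increase away from normal",
              var)
      }
    }
  }
  if (any(duplicated(def$categories$category))) {
    abort("scoring definition: duplicated diagnostic category names")
  }
  invisible(def)
}

# Vectorized band lookup with the gap-to-severe rule. Bands are sorted by
# lo; every table has open-ended extreme bands, so every value below the
# top band's lo lands in some band or an internal gap.
band_points <- function(values, bands) {
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  if (!any(ok)) return(out)
  v <- values[ok]
  idx <- findInterval(v, bands$lo)   # last band with lo <= v; >= 1 always
  inside <- v <= bands$hi[idx]
  pts <- ifelse(inside, bands$points[idx],
                pmax(bands$points[idx], bands$points[pmin(idx + 1L, nrow(bands))]))
  out[ok] <- as.integer(pts)
  out
}

check_domain <- function(variable, values) {
  dom <- apache2_domains()[[variable]]
  if (is.null(dom)) return(invisible())
  bad <- values[!is.na(values) & (values < dom[1] | values > dom[2])]
  if (length(bad) > 0) {
    stopf("APACHE II variable '%s': value %g outside validated domain [%g, %g]",
          variable, bad[1], dom[1], dom[2])
  }
}

#' Score one APACHE II physiologic component from its 24-hour extrema
#'
#' Returns the larger of the points earned by the recorded lowest and
#' highest value (the most deranged extremum), or `NA` when both extrema
#' are absent — deferred to the missingness strategy. Special rules:
#' neurologic points are `15 - GCS` (evaluated on the lowest recorded
#' scale), and creatinine points are doubled under acute renal failure.
#' Oxygenation is scored at the cohort level by [score_components()]
#' because it switches between `aado2` and `pao2` bands on FiO2.
#'
#' @param variable component name (a physiology table entry, or `"gcs"`).
#' @param lowest,highest numeric vectors of recorded extrema (`NA` = absent).
#' @param definition an [load_scoring_definition()] object.
#' @param acute_renal_failure logical vector; doubles creatinine points.
#' @return integer vector of points (`NA` where both extrema absent).
#' @export
score_component <- function(variable, lowest, highest, definition,
                            acute_renal_failure = FALSE) {
  n <- max(length(lowest), length(highest))
  lowest <- rep_len(lowest, n)
  highest <- rep_len(highest, n)
  check_domain(variable, c(lowest, highest))
  if (variable == "gcs") {
    gcs <- ifelse(!is.na(lowest), lowest, highest)
    return(as.integer(15 - gcs))
  }
  bands <- definition$physiology[[variable]]
  if (is.null(bands)) stopf("unknown APACHE II variable '%s'", variable)
  p <- pmax(band_points(lowest, bands), band_points(highest, bands), na.rm = TRUE)
  if (variable == "creatinine") {
    arf <- rep_len(as.logical(acute_renal_failure), n)
    p <- ifelse(!is.na(p) & arf, 2L * p, p)
  }
  as.integer(p)
}

#' Score all 12 APACHE II components for a wide extraction table
#'
#' Expects the column layout produced by [extract_first24h()]:
#' `<variable>_lowest` / `<variable>_highest` pairs, `pao2_lowest`,
#' `aado2_highest`, `fio2_highest`, `gcs_lowest`, and the logical
#' `acute_renal_failure`. Oxygenation uses the alveolar-arterial gradient
#' bands when FiO2 >= 0.5 and the arterial PaO2 bands otherwise (missing
#' FiO2 is read as < 0.5, the usual unventilated case).
#'
#' @param wide wide table, one row per admission.
#' @param definition an [load_scoring_definition()] object.
#' @param use_bicarbonate_fallback score serum bicarbonate in place of an
#'   absent arterial pH (off by default; both registries record blood gases).
#' @return tibble of integer component points, one column per component,
#'   `NA` where the component is unresolved.
#' @export
score_components <- function(wide, definition, use_bicarbonate_fallback = FALSE) {
  col <- function(nm) if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
  arf <- col("acute_renal_failure")
  arf <- !is.na(arf) & as.logical(arf)
  pts <- tibble::tibble(
    temperature = score_component("temperature", col("temperature_lowest"),
                                  col("temperature_highest"), definition),
    map = score_component("map", col("map_lowest"), col("map_highest"), definition),
    heart_rate = score_component("heart_rate", col("heart_rate_lowest"),
                                 col("heart_rate_highest"), definition),
    respiratory_rate = score_component("respiratory_rate",
                                       col("respiratory_rate_lowest"),
                                       col("respiratory_rate_highest"), definition),
    oxygenation = oxygenation_points(col("fio2_highest"), col("pao2_lowest"),
                                     col("aado2_highest"), definition),
    ph = score_component("ph", col("ph_lowest"), col("ph_highest"), definition),
    sodium = score_component("sodium", col("sodium_lowest"),
                             col("sodium_highest"), definition),
    potassium = score_component("potassium", col("potassium_lowest"),
                                col("potassium_highest"), definition),
    creatinine = score_component("creatinine", col("creatinine_lowest"),
                                 col("creatinine_highest"), definition,
                                 acute_renal_failure = arf),
    hematocrit = score_component("hematocrit", col("hematocrit_lowest"),
                                 col("hematocrit_highest"), definition),
    leukocytes = score_component("leukocytes", col("leukocytes_lowest"),
                                 col("leukocytes_highest"), definition),
    gcs = score_component("gcs", col("gcs_lowest"), col("gcs_highest"), definition)
  )
  if (use_bicarbonate_fallback) {
    fallback <- is.na(pts$ph)
    if (any(fallback)) {
      bic <- score_component("bicarbonate", col("bicarbonate_lowest"),
                             col("bicarbonate_highest"), definition)
      pts$ph[fallback] <- bic[fallback]
    }
  }
  pts
}

oxygenation_points <- function(fio2, pao2_low, aado2_high, definition) {
  check_domain("pao2", pao2_low)
  check_domain("aado2", aado2_high)
  use_aa <- !is.na(fio2) & fio2 >= 0.5
  p_aa <- band_points(aado2_high, definition$physiology$aado2)
  p_o2 <- band_points(pao2_low, definition$physiology$pao2)
  as.integer(ifelse(use_aa, p_aa, p_o2))
}

#' Acute physiology score, age and chronic-health points, total score
#'
#' All 12 components must be resolved (the missingness strategy — normal
#' fill or multiple imputation — runs first); an unresolved component is an
#' error, not a silent zero.
#'
#' @param components tibble of component points from [score_components()]
#'   (possibly after [normal_fill()]).
#' @param age integer years at admission.
#' @param severe_chronic logical: history of severe organ insufficiency or
#'   immunocompromise.
#' @param operative logical: postoperative admission.
#' @param elective_postop logical: elective postoperative admission.
#' @param definition an [load_scoring_definition()] object.
#' @return tibble with `aps`, `age_points`, `chronic_points`, `total`.
#' @export
compute_total <- function(components, age, severe_chronic, operative,
                          elective_postop, definition) {
  comp <- as.matrix(components[, apache2_components()])
  if (anyNA(comp)) {
    bad <- apache2_components()[which(colSums(is.na(comp)) > 0)]
    stopf("unresolved APACHE II component(s): %s (apply a missingness strategy first)",
          paste(bad, collapse = ", "))
  }
  aps <- as.integer(rowSums(comp))
  age_points <- band_points(age, definition$age)
  chronic_points <- ifelse(
    severe_chronic,
    ifelse(operative & elective_postop,
           definition$chronic$elective_postoperative,
           definition$chronic$nonoperative_or_emergency_postoperative),
    0L)
  total <- aps + age_points + as.integer(chronic_points)
  stopifnot(all(total >= 0 & total <= 71))
  tibble::tibble(aps = aps, age_points = as.integer(age_points),
                 chronic_points = as.integer(chronic_points), total = total)
}

#' Predicted ICU mortality risk from the APACHE II logistic model
#'
#' `logit(risk) = intercept + slope * total + emergency_term * 1(emergency
#' postoperative) + diagnostic category weight`.
#'
#' @param total integer APACHE II total score, in `[0, 71]`.
#' @param category_weight diagnostic-category logistic weight; an absent
#'   weight is an error (such admissions are excluded upstream).
#' @param emergency_postop logical.
#' @param definition an [load_scoring_definition()] object.
#' @return risk in (0, 1).
#' @export
mortality_risk <- function(total, category_weight, emergency_postop, definition) {
  if (any(is.na(total) | total < 0 | total > 71)) {
    abort("APACHE II total score must be in [0, 71]")
  }
  if (any(is.na(category_weight))) {
    abort("absent diagnostic category weight: admission should have been excluded")
  }
  lg <- definition$logistic
  eta <- lg$intercept + lg$score_coefficient * total +
    lg$emergency_surgery * as.numeric(emergency_postop) + category_weight
  plogis(eta)
}

#' Build a reason-for-admission diagnosis map
#'
#' A map takes each source vocabulary code to an APACHE II diagnostic
#' category, optionally chaining through an intermediate classification
#' (the two registries both route reasons for admission through an
#' intermediate classification before reaching APACHE II categories).
#'
#' @param entries data frame with `source_code` and either `category` or
#'   `intermediate_code` (the latter requires `via`).
#' @param via another `diagnosis_map` resolving the intermediate codes.
#' @param name vocabulary label.
#' @return a `diagnosis_map` object.
#' @export
diagnosis_map <- function(entries, via = NULL, name = "map") {
  entries <- tibble::as_tibble(entries)
  if (!"source_code" %in% names(entries)) abort("map needs a source_code column")
  if (!is.null(via)) {
    stopifnot(inherits(via, "diagnosis_map"))
    if (!"intermediate_code" %in% names(entries)) {
      abort("two-stage map needs an intermediate_code column")
    }
    hit <- match(entries$intermediate_code, via$entries$source_code)
    entries$category <- via$entries$category[hit]
  }
  if (!"category" %in% names(entries)) abort("map needs a category column")
  dup <- entries |>
    dplyr::distinct(.data$source_code, .data$category) |>
    dplyr::count(.data$source_code) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stopf("diagnosis map '%s': source code(s) %s map to multiple categories",
          name, paste(head(dup$source_code, 5), collapse = ", "))
  }
  structure(list(name = name,
                 entries = dplyr::distinct(entries, .data$source_code,
                                           .keep_all = TRUE)),
            class = "diagnosis_map")
}

#' Read a diagnosis map from delimited file(s)
#'
#' @param path CSV with `source_code,category` or
#'   `source_code,intermediate_code`.
#' @param via_path optional CSV resolving intermediate codes to categories.
#' @param name vocabulary label.
#' @return a `diagnosis_map` object.
#' @export
read_diagnosis_map <- function(path, via_path = NULL, name = basename(path)) {
  ent <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  via <- if (!is.null(via_path)) {
    diagnosis_map(readr::read_csv(via_path, show_col_types = FALSE, progress = FALSE),
                  name = basename(via_path))
  }
  diagnosis_map(ent, via = via, name = name)
}

#' Map reason-for-admission codes to APACHE II categories and weights
#'
#' Deterministic lookup; a code the map does not cover yields an explicit
#' `NA` category (unmapped marker) — never a default category. Such
#' admissions are excluded upstream.
#'
#' @param codes vector of source reason-for-admission codes.
#' @param map a [diagnosis_map()].
#' @param definition an [load_scoring_definition()] supplying category
#'   weights and operative flags.
#' @return tibble with `source_code`, `category`, `weight`, `operative`.
#' @export
map_reason <- function(codes, map, definition) {
  stopifnot(inherits(map, "diagnosis_map"))
  hit <- match(codes, map$entries$source_code)
  category <- map$entries$category[hit]
  cat_hit <- match(category, definition$categories$category)
  unknown <- !is.na(category) & is.na(cat_hit)
  if (any(unknown)) {
    stopf("diagnosis map '%s' targets unknown categor%s: %s", map$name,
          if (sum(unknown) > 1) "ies" else "y",
          paste(unique(category[unknown]), collapse = ", "))
  }
  tibble::tibble(
    source_code = codes,
    category = category,
    weight = definition$categories$weight[cat_hit],
    operative = definition$categories$operative[cat_hit]
  )
}
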