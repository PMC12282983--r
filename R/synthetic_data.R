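# Seeded synthetic OMOP stores with known ground truth.
#
# Each simulated patient draws a latent severity z ~ Normal(0, 1); every
# physiologic variable's worst first-24h value is a monotone map of z plus
# independent noise, so component derangements are positively correlated
# the way real organ failures are. Death is Bernoulli with probability
# min(1, multiplier x risk), where risk is the APACHE II risk of the
# generated values and the per-ICU multiplier is the true SMR the
# benchmark should recover (1.0 = on-target care). Two source "dialects"
# emulate the structural differences between the registries' OMOP builds:
# a different leukocyte concept code, comorbidities in
# condition_occurrence vs observation, different reason-for-admission
# vocabularies, and the v5.3 / v5.4 column-name dialect.

# Per-variable generative parameters: the normal-band centre, the far
# extreme reached at maximal derangement on each side, the probability
# that a patient's derangement is upward, the normal-band edges used for
# the benign opposite extremum, and recording precision (decimal places).
physiology_params <- function() {
  tibble::tribble(
    ~variable,          ~center, ~lo_extreme, ~hi_extreme, ~p_high, ~norm_lo, ~norm_hi, ~digits, ~shape_mult,
    "temperature",        37.1,      27.5,       42.2,      0.60,     36.0,    38.4,      1,       1.3,
    "map",                88,        32,        185,        0.35,     70,     109,        0,       1.3,
    "heart_rate",         88,        25,        195,        0.70,     70,     109,        0,       1.3,
    "respiratory_rate",   17,         2,         58,        0.80,     12,      24,        0,       1.3,
    "ph",                  7.41,      6.95,       7.78,     0.25,      7.33,    7.49,     2,       1.5,
    "sodium",            139,       102,        190,        0.40,    130,     149,        0,       1.4,
    "potassium",           4.2,       1.6,        7.8,      0.50,      3.5,     5.4,      1,       1.3,
    "creatinine",          1.0,       0.3,        6.5,      0.92,      0.6,     1.4,      1,       1.9,
    "hematocrit",         38,        14,         65,        0.20,     30,      45.9,      1,       1.3,
    "leukocytes",          8.5,       0.4,       48,        0.80,      3,      14.9,      1,       1.4
  )
}

# Default admission case mix over APACHE II diagnostic categories.
default_category_probs <- function() {
  c(nonop_sepsis = 0.10, nonop_respiratory_infection = 0.14,
    nonop_copd = 0.06, nonop_congestive_heart_failure = 0.07,
    nonop_post_cardiac_arrest = 0.04, nonop_multiple_trauma = 0.07,
    nonop_head_trauma = 0.05, nonop_intracranial_hemorrhage = 0.05,
    nonop_gi_bleeding = 0.06, nonop_diabetic_ketoacidosis = 0.04,
    nonop_drug_overdose = 0.04, postop_gi_neoplasm = 0.08,
    postop_peripheral_vascular = 0.06, postop_craniotomy_neoplasm = 0.05,
    postop_gi_perforation = 0.05, postop_respiratory_insufficiency = 0.04)
}

#' Describe one simulated data source (quality registry)
#'
#' @param name source label.
#' @param dialect `"A"` or `"B"`: which structural dialect the source's
#'   OMOP build uses (see [dialect_extraction_config()]).
#' @param n_icus number of ICUs.
#' @param patients_per_icu admissions per ICU.
#' @param smr_multipliers true SMR multiplier per ICU (recycled);
#'   `NULL` draws them from a lognormal with 0.2 log-sd around 1.
#' @param age_mean,age_sd adult age distribution (years, truncated 18-95).
#' @param male_fraction proportion male.
#' @param missingness list `(mechanism = "MCAR"|"MAR", rate, variables)`;
#'   `rate = 0` disables. Applied to whole per-admission variable blocks.
#' @return a `sim_source_spec` list.
#' @export
sim_source_spec <- function(name, dialect = c("A", "B"), n_icus = 8,
                            patients_per_icu = 250, smr_multipliers = 1,
                            age_mean = 58, age_sd = 16, male_fraction = 0.58,
                            missingness = list(mechanism = "MCAR", rate = 0,
                                               variables = character())) {
  dialect <- match.arg(dialect)
  stopifnot(n_icus >= 1, patients_per_icu >= 1,
            male_fraction >= 0, male_fraction <= 1,
            missingness$rate >= 0, missingness$rate <= 1)
  if (!is.null(smr_multipliers) && any(smr_multipliers <= 0)) {
    abort("smr_multipliers must be positive")
  }
  structure(list(name = name, dialect = dialect, n_icus = n_icus,
                 patients_per_icu = patients_per_icu,
                 smr_multipliers = smr_multipliers, age_mean = age_mean,
                 age_sd = age_sd, male_fraction = male_fraction,
                 missingness = missingness),
            class = "sim_source_spec")
}

#' Configure a synthetic benchmarking study
#'
#' Defaults emulate the study conditions: two registries with different
#' structural dialects, an older lower-mortality population in source A
#' and a younger higher-mortality one in source B, sparse missingness
#' assumed-normal in A (MCAR) and resource-driven severity-dependent
#' missingness in B (MAR).
#'
#' @param seed integer master seed; fixes every downstream draw.
#' @param sources list of [sim_source_spec()]s.
#' @param admission_window admission date window.
#' @param category_probs named simplex over APACHE II diagnostic
#'   categories.
#' @param elective_postop_prob probability an operative admission is
#'   elective (rest are emergency surgery).
#' @param severe_chronic_prob,arf_prob prevalence of the chronic-health
#'   and acute-renal-failure flags.
#' @param severity_loading correlation loading of each variable's
#'   derangement on the latent severity.
#' @param derangement_shape exponent concentrating derangements near
#'   normal (larger = healthier marginal population).
#' @param frac_minor,frac_burns,frac_missing_reason,frac_readmission,frac_outside_window,frac_hospital_death
#'   rates of admissions exercising each exclusion rule / outcome edge
#'   case.
#' @return a `sim_config` object.
#' @export
sim_config <- function(seed = 20190701,
                       sources = list(
                         sim_source_spec("registry_A", dialect = "A",
                                         age_mean = 64, age_sd = 13,
                                         male_fraction = 0.62,
                                         missingness = list(mechanism = "MCAR", rate = 0.05,
                                                            variables = lab_variables())),
                         sim_source_spec("registry_B", dialect = "B",
                                         age_mean = 52, age_sd = 17,
                                         male_fraction = 0.56,
                                         missingness = list(mechanism = "MAR", rate = 0.25,
                                                            variables = lab_variables()))),
                       admission_window = as.Date(c("2019-07-01", "2022-12-31")),
                       category_probs = default_category_probs(),
                       elective_postop_prob = 0.75,
                       severe_chronic_prob = 0.18, arf_prob = 0.06,
                       severity_loading = 0.6, derangement_shape = 3,
                       frac_minor = 0.02, frac_burns = 0.01,
                       frac_missing_reason = 0.02, frac_readmission = 0.03,
                       frac_outside_window = 0.02, frac_hospital_death = 0.02) {
  if (abs(sum(category_probs) - 1) > 1e-8 || any(category_probs < 0)) {
    abort("category_probs must be a simplex (nonnegative, summing to 1)")
  }
  if (admission_window[1] >= admission_window[2]) {
    abort("admission_window start must precede end")
  }
  probs <- c(frac_minor, frac_burns, frac_missing_reason, frac_readmission,
             frac_outside_window, frac_hospital_death, elective_postop_prob,
             severe_chronic_prob, arf_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(list(seed = as.integer(seed), sources = sources,
                 admission_window = as.Date(admission_window),
                 category_probs = category_probs,
                 elective_postop_prob = elective_postop_prob,
                 severe_chronic_prob = severe_chronic_prob, arf_prob = arf_prob,
                 severity_loading = severity_loading,
                 derangement_shape = derangement_shape,
                 frac_minor = frac_minor, frac_burns = frac_burns,
                 frac_missing_reason = frac_missing_reason,
                 frac_readmission = frac_readmission,
                 frac_outside_window = frac_outside_window,
                 frac_hospital_death = frac_hospital_death),
            class = "sim_config")
}

#' Laboratory component variables (the usual missingness targets)
#' @return character vector of variable names.
#' @export
lab_variables <- function() {
  c("ph", "sodium", "potassium", "creatinine", "hematocrit", "leukocytes")
}

#' Simulate per-admission ground truth without materializing OMOP tables
#'
#' The fast core of the generator: latent severity, true worst-in-24h
#' component values, APACHE II score and risk (computed by the package's
#' own scoring engine on the generated values), length of stay, and the
#' realized death indicator. [generate_store()] wraps this with OMOP event
#' materialization; statistical experiments (funnel coverage, SMR
#' recovery, imputation recovery) can use it directly.
#'
#' @param n number of admissions.
#' @param seed integer seed.
#' @param multiplier true SMR multiplier (scalar or per-admission vector).
#' @param age optional pre-drawn integer ages.
#' @param age_mean,age_sd,male_fraction,category_probs,elective_postop_prob,severe_chronic_prob,arf_prob,severity_loading,derangement_shape
#'   as in [sim_config()].
#' @param definition an [load_scoring_definition()]; defaults to the
#'   packaged one.
#' @return tibble, one row per admission, holding the wide-table component
#'   columns plus `z`, demographics, flags, `aps`, `total`, `risk`,
#'   `p_death`, `icu_death`, `icu_los_days`.
#' @export
simulate_truth <- function(n, seed, multiplier = 1, age = NULL,
                           age_mean = 58, age_sd = 16, male_fraction = 0.58,
                           category_probs = default_category_probs(),
                           elective_postop_prob = 0.75,
                           severe_chronic_prob = 0.18, arf_prob = 0.06,
                           severity_loading = 0.6, derangement_shape = 3,
                           definition = NULL) {
  definition <- definition %||% load_scoring_definition()
  cats <- names(category_probs)
  unknown <- setdiff(cats, definition$categories$category)
  if (length(unknown) > 0) {
    stopf("category_probs names unknown categor%s: %s",
          if (length(unknown) > 1) "ies" else "y", paste(unknown, collapse = ", "))
  }
  multiplier <- rep_len(multiplier, n)
  with_seed(seed, {
    z <- rnorm(n)
    if (is.null(age)) {
      age <- pmin(95L, pmax(18L, as.integer(round(rnorm(n, age_mean, age_sd)))))
    }
    sex <- ifelse(runif(n) < male_fraction, "male", "female")
    category <- sample(cats, n, replace = TRUE, prob = category_probs)
    cat_info <- definition$categories[match(category, definition$categories$category), ]
    operative <- cat_info$operative
    elective_postop <- operative & (runif(n) < elective_postop_prob)
    emergency_postop <- operative & !elective_postop
    severe_chronic <- runif(n) < severe_chronic_prob
    acute_renal_failure <- runif(n) < arf_prob

    ld <- severity_loading
    derange <- function(mult = 1) {
      pnorm(ld * z + sqrt(1 - ld^2) * rnorm(n))^(derangement_shape * mult)
    }
    wide <- tibble::tibble(.rows = n)
    pp <- physiology_params()
    for (i in seq_len(nrow(pp))) {
      p <- pp[i, ]
      f <- derange(p$shape_mult)
      up <- runif(n) < p$p_high
      worst <- ifelse(up, p$center + f * (p$hi_extreme - p$center),
                      p$center - f * (p$center - p$lo_extreme))
      benign <- ifelse(up, p$center - runif(n, 0, 0.6) * (p$center - p$norm_lo),
                       p$center + runif(n, 0, 0.6) * (p$norm_hi - p$center))
      hi <- round(pmax(worst, benign), p$digits)
      lo <- round(pmin(worst, benign), p$digits)
      wide[[paste0(p$variable, "_highest")]] <- hi
      wide[[paste0(p$variable, "_lowest")]] <- lo
    }
    # oxygenation: ventilated (FiO2 >= 0.5) patients carry an A-a gradient,
    # the rest an arterial PaO2
    fio2 <- round(pmin(1, 0.21 + 0.79 * derange(0.5)^0.5), 2)
    ventilated <- fio2 >= 0.5
    aado2 <- round(20 + derange(1.3) * 600)
    pao2 <- round(95 - derange(1.3) * (95 - 38))
    wide$fio2_highest <- fio2
    wide$aado2_highest <- ifelse(ventilated, aado2, NA_real_)
    wide$pao2_lowest <- ifelse(ventilated, NA_real_, pao2)
    wide$gcs_lowest <- pmax(3, pmin(15, 15 - round(12 * derange(1.5))))
    wide$acute_renal_failure <- acute_renal_failure

    pts <- score_components(wide, definition)
    totals <- compute_total(pts, age, severe_chronic, operative,
                            elective_postop, definition)
    risk <- mortality_risk(totals$total, cat_info$weight, emergency_postop,
                           definition)
    p_death <- pmin(1, multiplier * risk)
    death <- runif(n) < p_death
    los <- pmin(60, pmax(0.1, exp(rnorm(n, log(1.8) + 0.1 * z, 0.8)) / 1))
    # non-survivors leave at death, part-way through their projected stay
    los <- ifelse(death, pmax(0.05, los * runif(n, 0.15, 1)), los)

    dplyr::bind_cols(
      tibble::tibble(z = z, age = age, sex = sex, category = category,
                     weight = cat_info$weight, operative = operative,
                     elective_postop = elective_postop,
                     emergency_postop = emergency_postop,
                     severe_chronic = severe_chronic,
                     multiplier = multiplier),
      wide,
      totals,
      tibble::tibble(risk = risk, p_death = p_death, icu_death = death,
                     icu_los_days = los))
  })
}

# Solve the MAR intercept so that E[plogis(a + slope * z)] = rate for
# z ~ N(0,1); the logistic-in-severity link that makes sicker patients'
# values more often missing.
mar_intercept <- function(rate, slope = 1.2) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  marg <- function(a) {
    integrate(function(z) plogis(a + slope * z) * dnorm(z), -8, 8)$value - rate
  }
  uniroot(marg, c(-30, 30))$root
}

# Per-admission missingness probability under a missingness spec.
missingness_prob <- function(mechanism, rate, z, slope = 1.2) {
  if (mechanism == "MCAR") rep(rate, length(z))
  else plogis(mar_intercept(rate, slope) + slope * z)
}

#' Blank out component variables in a wide table (MCAR or MAR)
#'
#' Wide-table-level counterpart of [apply_missingness()]: sets the
#' `_highest`/`_lowest` columns of sampled (admission, variable) pairs to
#' `NA`. MAR deletion probability follows a logistic link in the latent
#' severity `z` with the intercept solved so the marginal rate matches.
#'
#' @param wide wide component table (e.g. from [simulate_truth()]).
#' @param z latent severity per row (required for MAR).
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate marginal per-variable missingness rate.
#' @param variables component variables to target.
#' @param seed integer seed.
#' @param slope MAR logistic slope on `z`.
#' @return `wide` with masked cells set to `NA`.
#' @export
mask_components <- function(wide, z, mechanism = c("MCAR", "MAR"), rate,
                            variables = lab_variables(), seed, slope = 1.2) {
  mechanism <- match.arg(mechanism)
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(wide)
  with_seed(seed, {
    for (v in variables) {
      p <- missingness_prob(mechanism, rate, z, slope)
      hit <- runif(nrow(wide)) < p
      for (col in paste0(v, c("_highest", "_lowest"))) {
        if (col %in% names(wide)) wide[[col]][hit] <- NA_real_
      }
    }
  })
  wide
}

#' Delete measurement events from a store (MCAR or MAR)
#'
#' Deletes all of a variable's measurement rows for sampled admissions, so
#' the per-admission per-variable missing fraction equals the configured
#' rate. MAR uses the same logistic-in-severity link as
#' [mask_components()].
#'
#' @param store an [omop_store()] produced by [generate_store()].
#' @param truth the matching truth table (supplies `z` per admission).
#' @param spec list `(mechanism, rate, variables)`.
#' @param seed integer seed.
#' @param slope MAR logistic slope.
#' @return the store with targeted measurement rows removed; the realized
#'   mask is attached as attribute `"missing_mask"`.
#' @export
apply_missingness <- function(store, truth, spec, seed, slope = 1.2) {
  stopifnot(inherits(store, "omop_store"))
  if (spec$rate == 0 || length(spec$variables) == 0) return(store)
  d <- dialect_concepts(attr(store, "dialect") %||% "A")
  masks <- with_seed(seed, {
    lapply(spec$variables, function(v) {
      p <- missingness_prob(spec$mechanism, spec$rate, truth$z, slope)
      tibble::tibble(variable = v,
                     visit_detail_id = truth$visit_detail_id[runif(nrow(truth)) < p],
                     concept_id = d$concepts[[v]])
    })
  })
  mask <- dplyr::bind_rows(masks)
  m <- store$measurement
  drop <- paste(m$measurement_concept_id, m$visit_detail_id) %in%
    paste(mask$concept_id, mask$visit_detail_id)
  store$measurement <- m[!drop, , drop = FALSE]
  attr(store, "missing_mask") <- mask
  store
}

#' Generate a synthetic benchmarking study: OMOP stores plus ground truth
#'
#' For each configured source, simulates admissions with known severity,
#' risk, and outcome, then materializes them as an OMOP CDM store in the
#' source's structural dialect: every admission gets 2-5 measurement
#' events per variable inside its first 24 hours whose extrema equal the
#' truth component values exactly (plus occasional more-deranged
#' distractor events after the window, which extraction must ignore),
#' reason-for-admission and admission-type observations, comorbidity
#' records in the dialect's table, and a death record inside the ICU stay
#' for non-survivors. A fixed seed reproduces the output byte for byte.
#'
#' @param config a [sim_config()].
#' @return a `sim_study` list: `sources` (named list with `store`,
#'   `truth`, `config` per source), `truth` (combined truth table), and
#'   `icu_truth` (per-ICU multiplier, observed and expected deaths over
#'   cohort-eligible admissions).
#' @export
generate_store <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  definition <- load_scoring_definition()
  seeds <- child_seeds(config$seed, 2 * length(config$sources))
  sources <- list()
  for (si in seq_along(config$sources)) {
    src <- config$sources[[si]]
    sources[[src$name]] <- generate_source(src, config, definition,
                                           truth_seed = seeds[2 * si - 1],
                                           event_seed = seeds[2 * si])
  }
  truth <- dplyr::bind_rows(lapply(sources, function(s) s$truth))
  icu_truth <- truth |>
    dplyr::filter(.data$in_cohort) |>
    dplyr::group_by(.data$source, .data$icu_id) |>
    dplyr::summarise(multiplier = .data$multiplier[1],
                     n = dplyr::n(),
                     observed = sum(.data$icu_death),
                     expected = sum(.data$risk), .groups = "drop")
  structure(list(sources = sources, truth = truth, icu_truth = icu_truth),
            class = "sim_study")
}

generate_source <- function(src, config, definition, truth_seed, event_seed) {
  n <- src$n_icus * src$patients_per_icu
  icu_id <- rep(seq_len(src$n_icus), each = src$patients_per_icu)
  mult <- with_seed(truth_seed + 7L, {
    m <- src$smr_multipliers %||% exp(rnorm(src$n_icus, 0, 0.2))
    rep_len(m, src$n_icus)
  })

  truth <- simulate_truth(
    n, seed = truth_seed, multiplier = mult[icu_id],
    age_mean = src$age_mean, age_sd = src$age_sd,
    male_fraction = src$male_fraction,
    category_probs = config$category_probs,
    elective_postop_prob = config$elective_postop_prob,
    severe_chronic_prob = config$severe_chronic_prob,
    arf_prob = config$arf_prob,
    severity_loading = config$severity_loading,
    derangement_shape = config$derangement_shape,
    definition = definition)
  truth$source <- src$name
  truth$icu_id <- icu_id
  truth$person_id <- seq_len(n)
  truth$visit_occurrence_id <- seq_len(n)
  truth$visit_detail_id <- seq_len(n)

  with_seed(event_seed, {
    # admissions exercising the exclusion rules
    special <- sample(c("none", "minor", "burns", "no_reason", "outside_window"),
                      n, replace = TRUE,
                      prob = c(1 - config$frac_minor - config$frac_burns -
                                 config$frac_missing_reason - config$frac_outside_window,
                               config$frac_minor, config$frac_burns,
                               config$frac_missing_reason, config$frac_outside_window))
    truth$age[special == "minor"] <- sample(5:16, sum(special == "minor"), TRUE)
    truth$exclusion <- ifelse(special == "none", NA_character_, special)
    truth$in_cohort <- special == "none"

    win <- as.POSIXct(config$admission_window, tz = "UTC")
    admit <- win[1] + runif(n) * as.numeric(difftime(win[2], win[1], units = "secs"))
    admit[special == "outside_window"] <-
      win[1] - runif(sum(special == "outside_window"), 1, 180) * 86400
    admit <- as.POSIXct(round(as.numeric(admit)), origin = "1970-01-01", tz = "UTC")
    discharge <- admit + round(truth$icu_los_days * 86400)
    truth$icu_admit <- admit
    truth$icu_discharge <- discharge

    death_dt <- as.POSIXct(ifelse(truth$icu_death, as.numeric(discharge), NA_real_),
                           origin = "1970-01-01", tz = "UTC")
    # a few survivors die on the ward after ICU discharge (hospital deaths,
    # which must NOT count as ICU mortality)
    ward <- !truth$icu_death & runif(n) < config$frac_hospital_death
    death_dt[ward] <- discharge[ward] + round(runif(sum(ward), 1, 10) * 86400)

    d <- dialect_concepts(src$dialect)
    person <- tibble::tibble(
      person_id = truth$person_id,
      gender_concept_id = ifelse(truth$sex == "male", 8507L, 8532L),
      year_of_birth = as.integer(format(admit, "%Y", tz = "UTC")) - truth$age)
    visit_occurrence <- tibble::tibble(
      visit_occurrence_id = truth$visit_occurrence_id,
      person_id = truth$person_id,
      visit_start_date = as.Date(admit, tz = "UTC") - sample(0:2, n, TRUE),
      visit_end_date = as.Date(discharge, tz = "UTC") + sample(0:5, n, TRUE),
      discharged_to_concept_id = NA_integer_)
    visit_detail <- tibble::tibble(
      visit_detail_id = truth$visit_detail_id,
      visit_occurrence_id = truth$visit_occurrence_id,
      person_id = truth$person_id,
      care_site_id = truth$icu_id,
      visit_detail_start_datetime = admit,
      visit_detail_end_datetime = discharge,
      discharged_to_concept_id = NA_integer_)

    # readmissions: a later second ICU stay inside the same hospital visit
    readmit <- which(truth$in_cohort & runif(n) < config$frac_readmission)
    if (length(readmit) > 0) {
      r_admit <- discharge[readmit] + round(runif(length(readmit), 0.5, 3) * 86400)
      r_disch <- r_admit + round(runif(length(readmit), 0.5, 4) * 86400)
      visit_detail <- dplyr::bind_rows(visit_detail, tibble::tibble(
        visit_detail_id = n + seq_along(readmit),
        visit_occurrence_id = truth$visit_occurrence_id[readmit],
        person_id = truth$person_id[readmit],
        care_site_id = truth$icu_id[readmit],
        visit_detail_start_datetime = r_admit,
        visit_detail_end_datetime = r_disch,
        discharged_to_concept_id = NA_integer_))
      visit_occurrence$visit_end_date[readmit] <-
        pmax(visit_occurrence$visit_end_date[readmit],
             as.Date(r_disch, tz = "UTC") + 1)
    }

    measurement <- build_measurements(truth, d, n)
    if (length(readmit) > 0) {
      # the second stay carries a token vital-sign series and a reason code
      r_ts <- visit_detail$visit_detail_start_datetime[n + seq_along(readmit)]
      measurement <- dplyr::bind_rows(measurement, tibble::tibble(
        person_id = truth$person_id[readmit],
        visit_detail_id = n + seq_along(readmit),
        measurement_concept_id = d$concepts$heart_rate,
        measurement_datetime = r_ts + 3600,
        value_as_number = round(runif(length(readmit), 75, 100)),
        unit_concept_id = d$units$heart_rate))
    }
    measurement$measurement_id <- seq_len(nrow(measurement))

    observation <- build_observations(truth, d, readmit,
                                      if (length(readmit) > 0) {
                                        visit_detail$visit_detail_start_datetime[n + seq_along(readmit)]
                                      })
    condition <- build_conditions(truth, d)
    death <- tibble::tibble(person_id = truth$person_id[!is.na(death_dt)],
                            death_datetime = death_dt[!is.na(death_dt)])

    store <- omop_store(
      list(person = person, visit_occurrence = visit_occurrence,
           visit_detail = visit_detail, measurement = measurement,
           observation = observation, condition_occurrence = condition,
           death = death),
      schema_version = d$schema_version, source_name = src$name)
    attr(store, "dialect") <- src$dialect
    if (src$missingness$rate > 0) {
      store <- apply_missingness(store, truth, src$missingness,
                                 seed = event_seed + 13L)
    }
    list(store = store, truth = truth,
         config = dialect_extraction_config(src$dialect, source_name = src$name,
                                            date_window = config$admission_window))
  })
}

# Materialize 2-5 timestamped measurement events per admission and numeric
# variable whose within-window extrema equal the truth values exactly;
# ~30% of variable blocks also get a more-deranged distractor event after
# the 24h window that extraction must exclude.
build_measurements <- function(truth, d, n) {
  pp <- physiology_params()
  out <- list()
  emit <- function(vd, value, offset_s, concept, unit) {
    tibble::tibble(person_id = truth$person_id[vd], visit_detail_id = vd,
                   measurement_concept_id = concept,
                   measurement_datetime = truth$icu_admit[vd] + offset_s,
                   value_as_number = value, unit_concept_id = unit)
  }
  two_sided <- function(var, digits, beyond) {
    hi <- truth[[paste0(var, "_highest")]]
    lo <- truth[[paste0(var, "_lowest")]]
    pres <- which(!is.na(hi))
    n_ev <- sample(2:5, length(pres), TRUE)
    vd <- rep(pres, n_ev)
    pos <- sequence(n_ev)
    val <- round(runif(length(vd), lo[vd], hi[vd]), digits)
    val[pos == 1] <- hi[vd[pos == 1]]
    val[pos == 2] <- lo[vd[pos == 2]]
    blocks <- emit(vd, val,
                   offset_s = round(runif(length(vd), 0, 24 * 3600 - 1)),
                   concept = d$concepts[[var]], unit = d$units[[var]])
    # out-of-window distractor, more deranged than the true worst
    dis <- pres[runif(length(pres)) < 0.3]
    if (length(dis) > 0) {
      up <- abs(hi[dis] - beyond$center) >= abs(lo[dis] - beyond$center)
      dval <- round(ifelse(up, pmin(beyond$hi_dom, hi[dis] + beyond$step),
                           pmax(beyond$lo_dom, lo[dis] - beyond$step)), digits)
      blocks <- dplyr::bind_rows(blocks, emit(
        dis, dval, offset_s = round(runif(length(dis), 24 * 3600, 30 * 3600)),
        concept = d$concepts[[var]], unit = d$units[[var]]))
    }
    blocks
  }
  for (i in seq_len(nrow(pp))) {
    p <- pp[i, ]
    dom <- apache2_domains()[[p$variable]]
    out[[p$variable]] <- two_sided(p$variable, p$digits,
                                   list(center = p$center,
                                        step = 0.06 * (p$hi_extreme - p$lo_extreme),
                                        lo_dom = dom[1], hi_dom = dom[2]))
  }
  one_sided <- function(var, values, spread, digits, unit, worse_up) {
    pres <- which(!is.na(values))
    n_ev <- sample(2:4, length(pres), TRUE)
    vd <- rep(pres, n_ev)
    first <- !duplicated(vd)
    jitter <- runif(length(vd), 0, spread) * ifelse(worse_up, -1, 1)
    val <- values[vd] + ifelse(first, 0, jitter)
    dom <- apache2_domains()[[if (var == "fio2") "aado2" else var]]
    val <- round(pmin(if (var == "fio2") 1 else dom[2],
                      pmax(if (var == "fio2") 0.21 else dom[1], val)), digits)
    emit(vd, val, offset_s = round(runif(length(vd), 0, 24 * 3600 - 1)),
         concept = d$concepts[[var]], unit = d$units[[var]])
  }
  out$fio2 <- one_sided("fio2", truth$fio2_highest, 0.15, 2, d$units$fio2, TRUE)
  out$aado2 <- one_sided("aado2", truth$aado2_highest, 80, 0, d$units$aado2, TRUE)
  out$pao2 <- one_sided("pao2", truth$pao2_lowest, 25, 0, d$units$pao2, FALSE)

  gcs <- truth$gcs_lowest
  n_ev <- sample(2:3, n, TRUE)
  vd <- rep(seq_len(n), n_ev)
  first <- !duplicated(vd)
  gval <- pmin(15, gcs[vd] + ifelse(first, 0, sample(0:3, length(vd), TRUE)))
  out$gcs <- emit(vd, gval, offset_s = round(runif(length(vd), 0, 24 * 3600 - 1)),
                  concept = d$concepts$gcs, unit = d$units$gcs)
  dplyr::bind_rows(out)
}

build_observations <- function(truth, d, readmit, readmit_ts) {
  reason_codes <- reason_code_lookup(d$dialect)
  keep <- is.na(truth$exclusion) | truth$exclusion != "no_reason"
  obs <- list(
    tibble::tibble(person_id = truth$person_id[keep],
                   visit_detail_id = truth$visit_detail_id[keep],
                   observation_concept_id = d$concepts$reason,
                   observation_datetime = truth$icu_admit[keep],
                   value_as_number = as.numeric(reason_codes[truth$category[keep]]),
                   unit_concept_id = NA_integer_))
  flag_obs <- function(mask, concept) {
    tibble::tibble(person_id = truth$person_id[mask],
                   visit_detail_id = truth$visit_detail_id[mask],
                   observation_concept_id = concept,
                   observation_datetime = truth$icu_admit[mask],
                   value_as_number = 1, unit_concept_id = NA_integer_)
  }
  obs <- c(obs, list(flag_obs(truth$elective_postop, d$concepts$elective_postop),
                     flag_obs(truth$emergency_postop, d$concepts$emergency_postop)))
  if (d$comorbidity_table == "observation") {
    obs <- c(obs, list(flag_obs(truth$severe_chronic, d$concepts$severe_chronic),
                       flag_obs(truth$acute_renal_failure,
                                d$concepts$acute_renal_failure)))
  }
  if (length(readmit) > 0) {
    obs <- c(obs, list(tibble::tibble(
      person_id = truth$person_id[readmit],
      visit_detail_id = nrow(truth) + seq_along(readmit),
      observation_concept_id = d$concepts$reason,
      observation_datetime = readmit_ts,
      value_as_number = as.numeric(reason_codes[truth$category[readmit]]),
      unit_concept_id = NA_integer_)))
  }
  res <- dplyr::bind_rows(obs)
  res$observation_id <- seq_len(nrow(res))
  res
}

build_conditions <- function(truth, d) {
  cond <- list()
  add_cond <- function(mask, concept) {
    tibble::tibble(person_id = truth$person_id[mask],
                   visit_detail_id = truth$visit_detail_id[mask],
                   condition_concept_id = concept,
                   condition_start_datetime = truth$icu_admit[mask])
  }
  burns <- !is.na(truth$exclusion) & truth$exclusion == "burns"
  cond <- c(cond, list(add_cond(burns, d$concepts$burns)))
  if (d$comorbidity_table == "condition_occurrence") {
    cond <- c(cond, list(add_cond(truth$severe_chronic, d$concepts$severe_chronic),
                         add_cond(truth$acute_renal_failure,
                                  d$concepts$acute_renal_failure)))
  }
  res <- dplyr::bind_rows(cond)
  res$condition_occurrence_id <- seq_len(max(1, nrow(res)))[seq_len(nrow(res))]
  res
}

# category -> reason-for-admission source code in a dialect's vocabulary.
reason_code_lookup <- function(dialect) {
  a <- readr::read_csv(system.file("extdata", "synthetic_reason_map_apacheiv.csv",
                                   package = "icubench"),
                       show_col_types = FALSE, progress = FALSE)
  if (dialect == "A") {
    setNames(a$source_code, a$category)
  } else {
    b <- readr::read_csv(system.file("extdata", "synthetic_reason_map_snomed.csv",
                                     package = "icubench"),
                         show_col_types = FALSE, progress = FALSE)
    cat_of <- setNames(a$category, a$source_code)
    setNames(b$source_code, cat_of[as.character(b$intermediate_code)])
  }
}

#' Diagnosis map matching a synthetic dialect
#'
#' Dialect A codes reasons for admission in an APACHE-IV-like intermediate
#' vocabulary mapped directly to APACHE II categories; dialect B uses
#' SNOMED-like codes chained through that intermediate classification.
#' Both mapping tables are synthetic stand-ins shipped with the package.
#'
#' @param dialect `"A"` or `"B"`.
#' @return a [diagnosis_map()].
#' @export
dialect_diagnosis_map <- function(dialect = c("A", "B")) {
  dialect <- match.arg(dialect)
  a_path <- system.file("extdata", "synthetic_reason_map_apacheiv.csv",
                        package = "icubench")
  if (dialect == "A") {
    read_diagnosis_map(a_path, name = "synthetic_apacheiv")
  } else {
    read_diagnosis_map(system.file("extdata", "synthetic_reason_map_snomed.csv",
                                   package = "icubench"),
                       via_path = a_path, name = "synthetic_snomed")
  }
}
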