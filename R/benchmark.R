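# Observed/expected deaths, standardized mortality ratios, funnel-plot
# control limits, Rubin-pooled registry funnels, and the demographics
# report.

#' Expected deaths from predicted risks
#'
#' The expected mortality of a unit is the mean of its patients' predicted
#' mortality risks multiplied by the number of patients — identically the
#' sum of the risks.
#'
#' @param risks predicted mortality risks in (0, 1).
#' @return sum of risks.
#' @export
expected_deaths <- function(risks) {
  if (length(risks) == 0) abort("expected_deaths: empty risk vector")
  if (any(is.na(risks) | risks <= 0 | risks >= 1)) {
    abort("risks must lie strictly inside (0, 1)")
  }
  sum(risks)
}

#' Observed deaths, expected deaths, and SMR per unit
#'
#' Aggregates scored admissions to ICU or quality-registry level. The
#' registry SMR is (sum of observed) / (sum of expected) over its ICUs —
#' a ratio of totals, not a mean of ICU SMRs.
#'
#' @param scored tibble with one row per admission: `source` (registry),
#'   `icu_id`, logical `icu_death`, `risk`.
#' @param level `"registry"` or `"icu"`.
#' @return tibble of unit statistics: `n_admissions`, `observed`,
#'   `expected`, `smr` (`NA` with a warning if a unit has zero expected
#'   deaths).
#' @export
compute_smr <- function(scored, level = c("registry", "icu")) {
  level <- match.arg(level)
  keys <- if (level == "icu") c("source", "icu_id") else "source"
  out <- scored |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_admissions = dplyr::n(),
                     observed = sum(.data$icu_death),
                     expected = sum(.data$risk), .groups = "drop")
  if (any(out$expected <= 0)) {
    warn("unit(s) with zero expected deaths: SMR reported as NA")
  }
  out$smr <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  out
}

# Continuity-interpolated Poisson tail quantile: the piecewise-linear
# inverse of the Poisson CDF joined at the integers, so that the stated
# coverage of the funnel limits is approximately nominal rather than
# conservative. Vectorized over E.
poisson_interp_quantile <- function(p, E) {
  k <- qpois(p, E)
  Fk <- ppois(k, E)
  Fk1 <- ppois(k - 1, E)
  # guard numeric edges where qpois over/undershoots the target
  over <- Fk1 >= p
  while (any(over)) {
    k[over] <- k[over] - 1L
    Fk[over] <- ppois(k[over], E[over])
    Fk1[over] <- ppois(k[over] - 1, E[over])
    over <- Fk1 >= p & k > 0
  }
  (k - 1) + (p - Fk1) / (Fk - Fk1)
}

#' Funnel-plot control limits under the null SMR = 1
#'
#' Under the null the observed deaths of a unit with expected deaths E
#' behave as Poisson(E); the limits divide the interpolated alpha/2 and
#' 1 - alpha/2 Poisson tail quantiles by E. They bracket 1 everywhere,
#' widen as E shrinks (no single "normal" SMR value), and tend to 1 as E
#' grows.
#'
#' @param E_grid positive expected-death values.
#' @param alpha two-sided false-alarm rate (default 0.05 for 95% limits).
#' @return tibble `expected`, `lower`, `upper` with attribute `alpha`.
#' @export
funnel_limits <- function(E_grid, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (any(E_grid <= 0)) abort("expected deaths must be positive")
  lower <- pmax(0, poisson_interp_quantile(alpha / 2, E_grid)) / E_grid
  upper <- poisson_interp_quantile(1 - alpha / 2, E_grid) / E_grid
  structure(tibble::tibble(expected = E_grid, lower = lower, upper = upper),
            alpha = alpha)
}

#' Flag units outside their funnel control limits
#'
#' @param stats unit statistics from [compute_smr()].
#' @param alpha two-sided false-alarm rate.
#' @return `stats` with `lower`, `upper`, and `status`
#'   (`"below"` / `"in_control"` / `"above"`).
#' @export
funnel_outliers <- function(stats, alpha = 0.05) {
  lim <- funnel_limits(stats$expected, alpha)
  stats$lower <- lim$lower
  stats$upper <- lim$upper
  stats$status <- dplyr::case_when(
    stats$smr > stats$upper ~ "above",
    stats$smr < stats$lower ~ "below",
    TRUE ~ "in_control")
  stats
}

#' Rubin-pooled registry statistics under multiple imputation
#'
#' Expected deaths are computed separately on each imputed dataset and
#' combined with Rubin's rules; observed deaths do not vary across
#' imputations. The within-imputation variance of expected deaths is
#' `sum(R_i (1 - R_i))`, treating risks as independent Bernoulli means.
#' SMR interval endpoints are order-reversing in E: `smr_lo95 = O / E_hi`,
#' `smr_hi95 = O / E_lo`.
#'
#' @param scored_list per-imputation scored admission tables (as for
#'   [compute_smr()]).
#' @param level `"registry"` or `"icu"`.
#' @return list with `stats` (per unit: pooled `expected`, `smr`,
#'   `smr_lo95`, `smr_hi95`, per-imputation spread) and `limits` — funnel
#'   control limits evaluated for the pooled point and both interval
#'   bounds of E (the three funnel overlays).
#' @export
pooled_funnel <- function(scored_list, level = c("registry", "icu")) {
  level <- match.arg(level)
  m <- length(scored_list)
  per_imp <- lapply(scored_list, function(s) {
    keys <- if (level == "icu") c("source", "icu_id") else "source"
    s |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(n_admissions = dplyr::n(),
                       observed = sum(.data$icu_death),
                       E = sum(.data$risk),
                       V = sum(.data$risk * (1 - .data$risk)),
                       .groups = "drop")
  })
  units <- per_imp[[1]][, setdiff(names(per_imp[[1]]), c("E", "V"))]
  pooled <- lapply(seq_len(nrow(units)), function(i) {
    est <- vapply(per_imp, function(x) x$E[i], 1.0)
    vr <- vapply(per_imp, function(x) x$V[i], 1.0)
    p <- rubin_pool(est, vr)
    tibble::tibble(expected = p$point, expected_lo95 = p$ci95[1],
                   expected_hi95 = p$ci95[2], between_var = p$between,
                   mi_degenerate = isTRUE(p$degenerate) ||
                     (!is.na(p$between) && p$between == 0))
  })
  stats <- dplyr::bind_cols(units, dplyr::bind_rows(pooled))
  stats$smr <- stats$observed / stats$expected
  stats$smr_lo95 <- stats$observed / stats$expected_hi95
  stats$smr_hi95 <- stats$observed / pmax(stats$expected_lo95, 1e-12)
  grid_for <- function(E) funnel_limits(sort(unique(pmax(E, 1e-9))))
  list(stats = stats,
       limits = list(point = grid_for(stats$expected),
                     lower = grid_for(stats$expected_lo95),
                     upper = grid_for(stats$expected_hi95)),
       m = m)
}

#' Demographics and outcomes report
#'
#' Per source: number of ICUs and patients, median (IQR) age, male N (%),
#' median (IQR) APACHE II score, ICU mortality N (%), median (IQR) ICU
#' length of stay. Percentages are 100 x count / total, rounded half-up
#' to one decimal; IQRs are 25th-75th percentiles.
#'
#' @param scored tibble with one row per scored admission: `source`,
#'   `icu_id`, `age`, `sex`, `total`, `icu_death`, `icu_los_days`.
#' @return one-row-per-source tibble.
#' @export
demographics_table <- function(scored) {
  med_iqr <- function(x) {
    q <- round_half_up(quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE,
                                names = FALSE), 1)
    tibble::tibble(median = q[1], q1 = q[2], q3 = q[3])
  }
  scored |>
    dplyr::group_by(.data$source) |>
    dplyr::group_modify(function(df, key) {
      dplyr::bind_cols(
        tibble::tibble(n_icus = dplyr::n_distinct(df$icu_id),
                       n_patients = nrow(df)),
        setNames(med_iqr(df$age), paste0("age_", c("median", "q1", "q3"))),
        tibble::tibble(male_n = sum(df$sex == "male"),
                       male_pct = pct_1dp(sum(df$sex == "male"), nrow(df))),
        setNames(med_iqr(df$total),
                 paste0("apache2_", c("median", "q1", "q3"))),
        tibble::tibble(icu_mortality_n = sum(df$icu_death),
                       icu_mortality_pct = pct_1dp(sum(df$icu_death), nrow(df))),
        setNames(med_iqr(df$icu_los_days),
                 paste0("icu_los_", c("median", "q1", "q3"))))
    }) |>
    dplyr::ungroup()
}

#' Render a funnel plot
#'
#' Each unit is a dot at (expected deaths, SMR); the horizontal centre
#' line is the null SMR of 1; curved lines are the control limits. When
#' `path` ends in `.svg` or `.png` the plot is written there with the
#' cairo device.
#'
#' @param stats unit statistics from [compute_smr()] or
#'   [pooled_funnel()]`$stats`.
#' @param limits a [funnel_limits()] table (defaults to limits over a
#'   smooth grid spanning the data).
#' @param path optional output file.
#' @param alpha used when `limits` is `NULL`.
#' @return the ggplot object, invisibly.
#' @export
plot_funnel <- function(stats, limits = NULL, path = NULL, alpha = 0.05) {
  if (nrow(stats) == 0) abort("no unit statistics to plot")
  if (is.null(limits)) {
    grid <- seq(max(0.5, min(stats$expected) * 0.5),
                max(stats$expected) * 1.1, length.out = 200)
    limits <- funnel_limits(grid, alpha)
  }
  p <- ggplot2::ggplot(stats, ggplot2::aes(x = .data$expected, y = .data$smr)) +
    ggplot2::geom_line(data = limits,
                       ggplot2::aes(x = .data$expected, y = .data$lower),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(data = limits,
                       ggplot2::aes(x = .data$expected, y = .data$upper),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey20") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Expected number of deaths",
                  y = "Standardized mortality ratio") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    switch(ext,
      svg = grDevices::svg(path, width = 7, height = 5),
      png = grDevices::png(path, width = 1400, height = 1000, res = 200),
      stopf("unsupported funnel plot format '%s' (use .svg or .png)", ext))
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}
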