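# The two context-specific missing-data strategies.
#
# Strategy 1 (registries whose clinicians leave presumed-normal values
# unmeasured): an absent physiologic component scores 0 points — the
# normal-range fill of the original severity model. No raw values are
# invented; the fill acts on points.
#
# Strategy 2 (registries where missingness reflects resource constraints):
# multiple imputation by chained equations with predictive mean matching
# (PMM), pooled with Rubin's rules. PMM is hot-deck: every imputed value
# is an observed donor value from a case with a near regression-predicted
# mean, so imputations respect the variable's support.

#' Resolve absent components at zero weight (normal-range fill)
#'
#' Scores the recorded components and maps every absent one to 0 points:
#' the patient's unmeasured variable is presumed normal and contributes no
#' risk. Because the fill acts on points, filling and scoring commute.
#'
#' @param wide wide extraction table (see [extract_first24h()]).
#' @param definition an [load_scoring_definition()].
#' @param use_bicarbonate_fallback passed to [score_components()].
#' @return tibble of fully resolved integer component points.
#' @export
normal_fill <- function(wide, definition, use_bicarbonate_fallback = FALSE) {
  pts <- score_components(wide, definition, use_bicarbonate_fallback)
  for (v in names(pts)) pts[[v]][is.na(pts[[v]])] <- 0L
  pts
}

#' Multiple-imputation settings
#'
#' Defaults follow the analysis convention of 30 imputations with 100
#' chained-equation cycles each and 5 PMM donors.
#'
#' @param m number of imputations.
#' @param iterations chained-equation cycles per imputation.
#' @param donors_k PMM donor pool size.
#' @param seed integer seed; each imputation chain gets a distinct
#'   sub-seed.
#' @param variables columns to impute; `NULL` = every `_highest`/`_lowest`
#'   component column with missing cells except the structurally
#'   conditional oxygenation columns (`pao2_lowest`, `aado2_highest`),
#'   whose absence encodes ventilation status, not a data gap.
#' @return an `mi_config` list.
#' @export
mi_config <- function(m = 30, iterations = 100, donors_k = 5, seed = 1,
                      variables = NULL) {
  stopifnot(m >= 1, iterations >= 1, donors_k >= 1)
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 donors_k = as.integer(donors_k), seed = as.integer(seed),
                 variables = variables),
            class = "mi_config")
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Per cycle, each incomplete variable (in fixed column order) is
#' regressed on the current completed predictors over its observed rows;
#' regression coefficients are drawn from their posterior under the
#' standard noninformative prior (proper imputation requires parameter
#' uncertainty); each missing row is matched to the `donors_k` observed
#' rows with nearest predicted mean — observed rows predicted under the
#' posterior-mean coefficients, missing rows under the drawn ones — and
#' receives a uniformly drawn donor's observed value. Predictors are the
#' quality registry (`source` column, when several), ICU survival status,
#' ICU length of stay, and the component variables themselves.
#'
#' @param wide wide table with component columns, `icu_death`,
#'   `icu_los_days`, optionally `source`.
#' @param mi an [mi_config()].
#' @return an `imputation_set`: list with `completed` (m wide tables,
#'   observed cells identical across all copies), `variables`, and the
#'   config.
#' @export
mi_pmm <- function(wide, mi) {
  stopifnot(inherits(mi, "mi_config"))
  comp_cols <- grep("_(highest|lowest)$", names(wide), value = TRUE)
  targets <- mi$variables %||% {
    has_na <- comp_cols[vapply(comp_cols, function(c) anyNA(wide[[c]]), TRUE)]
    setdiff(has_na, c("pao2_lowest", "aado2_highest", "fio2_highest"))
  }
  if (length(targets) == 0) {
    return(structure(list(completed = rep(list(wide), mi$m),
                          variables = character(), config = mi),
                     class = "imputation_set"))
  }
  for (v in targets) {
    n_obs <- sum(!is.na(wide[[v]]))
    if (n_obs < mi$donors_k) {
      stopf("variable '%s' has %d observed rows, fewer than donors_k = %d",
            v, n_obs, mi$donors_k)
    }
  }
  for (c in c("icu_death", "icu_los_days")) {
    if (!c %in% names(wide)) stopf("mi_pmm predictors require column '%s'", c)
  }

  # numeric predictor matrix: outcome, length of stay, registry dummies,
  # and every fully observed or target component column
  base <- cbind(icu_death = as.numeric(wide$icu_death),
                icu_los_days = wide$icu_los_days)
  if ("source" %in% names(wide) && length(unique(wide$source)) > 1) {
    lev <- sort(unique(wide$source))[-1]
    for (l in lev) base <- cbind(base, as.numeric(wide$source == l))
  }
  complete_comp <- setdiff(comp_cols[vapply(comp_cols, function(c) !anyNA(wide[[c]]), TRUE)],
                           targets)
  pred_cols <- c(complete_comp, targets)
  mat0 <- cbind(base, as.matrix(wide[, pred_cols, drop = FALSE]))
  colnames(mat0) <- c(colnames(base), pred_cols)
  mis_idx <- lapply(targets, function(v) which(is.na(wide[[v]])))
  names(mis_idx) <- targets

  seeds <- child_seeds(mi$seed, mi$m)
  completed <- lapply(seq_len(mi$m), function(j) {
    with_seed(seeds[j], {
      mat <- mat0
      # initialize missing cells from the observed marginal
      for (v in targets) {
        mis <- mis_idx[[v]]
        if (length(mis) == 0) next
        obs_vals <- mat[-mis, v]
        mat[mis, v] <- obs_vals[sample.int(length(obs_vals), length(mis),
                                           replace = TRUE)]
      }
      for (it in seq_len(mi$iterations)) {
        for (v in targets) {
          mis <- mis_idx[[v]]
          if (length(mis) == 0) next
          y_obs <- wide[[v]][-mis]
          X <- cbind(1, mat[, setdiff(colnames(mat), v), drop = FALSE])
          mat[mis, v] <- pmm_impute(X[-mis, , drop = FALSE], y_obs,
                                    X[mis, , drop = FALSE], mi$donors_k)
        }
      }
      out <- wide
      for (v in targets) out[[v]][mis_idx[[v]]] <- mat[mis_idx[[v]], v]
      out
    })
  })
  structure(list(completed = completed, variables = targets, config = mi),
            class = "imputation_set")
}

# One PMM update: Bayesian linear-model draw, predictive means, k-nearest
# donor match on the sorted prediction line, uniform donor draw.
pmm_impute <- function(X_obs, y_obs, X_mis, k) {
  p <- ncol(X_obs)
  n_obs <- nrow(X_obs)
  XtX <- crossprod(X_obs)
  R <- chol(XtX + diag(1e-6 * pmax(diag(XtX), 1), p))
  V <- chol2inv(R)
  betahat <- V %*% crossprod(X_obs, y_obs)
  resid <- y_obs - X_obs %*% betahat
  df <- max(n_obs - p, 1)
  sigma2 <- sum(resid^2) / rchisq(1, df)
  beta_star <- betahat + t(chol((V + t(V)) / 2)) %*% rnorm(p) * sqrt(sigma2)
  yhat_obs <- drop(X_obs %*% betahat)
  yhat_mis <- drop(X_mis %*% beta_star)

  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  donors <- y_obs[ord]
  n_mis <- length(yhat_mis)
  # the k nearest neighbours on a sorted line form a contiguous window;
  # grow it one step at a time toward the nearer side (vectorized over rows)
  l <- findInterval(yhat_mis, ys)
  r <- l + 1L
  for (step in seq_len(k)) {
    dl <- ifelse(l >= 1L, yhat_mis - ys[pmax(l, 1L)], Inf)
    dr <- ifelse(r <= n_obs, ys[pmin(r, n_obs)] - yhat_mis, Inf)
    left <- dl <= dr
    l <- l - as.integer(left)
    r <- r + as.integer(!left)
  }
  pick <- l + 1L + floor(runif(n_mis) * k)
  donors[pick]
}

#' Pool multiply imputed estimates with Rubin's rules
#'
#' Point estimate = mean of the per-imputation estimates; total variance
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and
#' `B` the between-imputation variance; the 95% interval uses a t
#' reference with `nu = (m - 1) (1 + W / ((1 + 1/m) B))^2` degrees of
#' freedom (normal reference when `B = 0`).
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation (within) variances.
#' @return a `pooled_estimate` list: `point`, `within`, `between`,
#'   `total`, `df`, `ci95`, `m`, and `degenerate` (`TRUE` when `m = 1`,
#'   where the between-variance is undefined and `T = W`).
#' @export
rubin_pool <- function(estimates, variances) {
  if (length(estimates) != length(variances)) {
    abort("estimates and variances must have the same length")
  }
  m <- length(estimates)
  if (m < 1) abort("need at least one estimate")
  point <- mean(estimates)
  W <- mean(variances)
  if (m == 1) {
    return(structure(list(point = point, within = W, between = NA_real_,
                          total = W, df = Inf,
                          ci95 = point + c(-1, 1) * qnorm(0.975) * sqrt(W),
                          m = 1L, degenerate = TRUE),
                     class = "pooled_estimate"))
  }
  B <- var(estimates)
  total <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    half <- stats::qt(0.975, df) * sqrt(total)
  } else {
    df <- Inf
    half <- qnorm(0.975) * sqrt(total)
  }
  structure(list(point = point, within = W, between = B, total = total,
                 df = df, ci95 = point + c(-1, 1) * half, m = as.integer(m),
                 degenerate = FALSE),
            class = "pooled_estimate")
}
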