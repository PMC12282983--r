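def <- scoring_def()

test_that("normal fill resolves absent components at exactly zero points", {
  # everything missing -> APS 0
  empty <- vignette_wide()
  pts <- normal_fill(empty, def)
  expect_equal(sum(unlist(pts)), 0L)
  expect_false(anyNA(unlist(pts)))

  # only potassium missing -> APS is the sum of the 11 scored components
  w <- vignette_wide(temperature = 39.5, map = 120, heart_rate = 145,
                     respiratory_rate = 30, fio2 = 0.21, pao2 = 65,
                     ph = 7.30, sodium = 152, creatinine = 2.2,
                     hematocrit = 28, leukocytes = 21, gcs = 12)
  pts <- normal_fill(w, def)
  expect_equal(pts$potassium, 0L)
  expect_equal(sum(unlist(pts)), 24L - 1L)  # vignette 1 minus potassium's 1

  # the fill never decreases the observed-components score
  raw <- score_components(w, def)
  expect_true(all(unlist(pts) >= unlist(lapply(raw, function(x) {
    x[is.na(x)] <- 0L
    x
  }))))
})

test_that("filling then scoring equals scoring then filling on random tables", {
  tr <- simulate_truth(300, seed = 612)
  masked <- mask_components(tr, tr$z, "MCAR", rate = 0.4,
                            variables = lab_variables(), seed = 613)
  a <- normal_fill(masked, def)
  b <- score_components(masked, def)
  for (v in names(b)) b[[v]][is.na(b[[v]])] <- 0L
  expect_equal(a, b)
})

test_that("PMM with nothing missing returns m identical copies", {
  tr <- simulate_truth(60, seed = 7)
  imp <- mi_pmm(tr, mi_config(m = 3, iterations = 2, seed = 2))
  expect_length(imp$completed, 3)
  for (w in imp$completed) expect_equal(w, tr)
})

test_that("PMM is hot-deck, deterministic, and leaves observed cells untouched", {
  tr <- simulate_truth(400, seed = 21)
  masked <- mask_components(tr, tr$z, "MAR", rate = 0.3,
                            variables = lab_variables(), seed = 22)
  cfg <- mi_config(m = 2, iterations = 3, seed = 23)
  imp <- mi_pmm(masked, cfg)
  imp2 <- mi_pmm(masked, cfg)
  expect_equal(imp$completed, imp2$completed)   # seed determinism
  for (v in paste0(lab_variables(), "_highest")) {
    mis <- which(is.na(masked[[v]]))
    obs <- masked[[v]][-mis]
    for (w in imp$completed) {
      # observed cells identical across copies
      expect_equal(w[[v]][-mis], obs)
      # every imputed value is an observed donor value
      expect_true(all(w[[v]][mis] %in% obs))
      expect_false(anyNA(w[[v]]))
    }
  }
  # the two imputations differ somewhere (parameter uncertainty is real)
  expect_false(isTRUE(all.equal(imp$completed[[1]], imp$completed[[2]])))
})

test_that("donors_k = 1 with a perfectly informative predictor returns the nearest donor", {
  # y equals x for observed rows; the missing row's x = 4.02 sits nearest
  # the donor with x = 4 -> imputation must be exactly that donor's y
  wide <- tibble::tibble(
    temperature_highest = c(1, 2, 3, 4, 10, 4.02),
    temperature_lowest = c(1, 2, 3, 4, 10, 4.02),
    sodium_highest = c(1, 2, 3, 4, 10, NA),
    icu_death = FALSE, icu_los_days = 1)
  wide$sodium_lowest <- wide$sodium_highest
  imp <- mi_pmm(wide, mi_config(m = 5, iterations = 3, donors_k = 1, seed = 5,
                                variables = c("sodium_highest", "sodium_lowest")))
  for (w in imp$completed) expect_equal(w$sodium_highest[6], 4)
})

test_that("an incomplete variable with fewer observed rows than donors_k is fatal", {
  wide <- tibble::tibble(temperature_highest = c(1, 2, NA, NA, NA, NA),
                         icu_death = FALSE, icu_los_days = 1)
  expect_error(mi_pmm(wide, mi_config(m = 1, iterations = 1, donors_k = 5,
                                      variables = "temperature_highest")),
               "temperature_highest.*donors_k")
})

test_that("Rubin pooling reproduces the hand-worked example and its invariants", {
  p <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$point, 2)
  expect_equal(p$within, 1)
  expect_equal(p$between, 1)
  expect_equal(p$total, 7 / 3)
  expect_equal(p$df, 2 * (1 + 1 / (4 / 3))^2)

  # identical estimates: B = 0, T = W, point = the common value
  p0 <- rubin_pool(c(5, 5, 5), c(2, 2, 2))
  expect_equal(p0$between, 0)
  expect_equal(p0$total, p0$within)
  expect_equal(p0$point, 5)

  # permutation invariance
  perm <- rubin_pool(c(3, 1, 2), c(1, 1, 1))
  expect_equal(perm$total, p$total)
  expect_equal(perm$point, p$point)

  # T >= W always on random inputs
  set.seed(1)
  for (i in 1:20) {
    est <- rnorm(5)
    va <- runif(5, 0.1, 2)
    pp <- rubin_pool(est, va)
    expect_gte(pp$total, pp$within)
    expect_equal(pp$point, mean(est))
  }

  # m = 1: between-variance undefined, flagged, T collapses to W
  p1 <- rubin_pool(4, 2)
  expect_true(p1$degenerate)
  expect_equal(p1$total, p1$within)
  expect_error(rubin_pool(c(1, 2), 1), "same length")
})
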