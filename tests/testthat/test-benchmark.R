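test_that("expected deaths is the sum of risks (= mean x n)", {
  expect_equal(expected_deaths(rep(0.1, 100)), 10)
  set.seed(4)
  for (i in 1:5) {
    r <- runif(50, 0.01, 0.9)
    expect_equal(expected_deaths(r), mean(r) * length(r))
  }
  expect_error(expected_deaths(numeric()), "empty")
  expect_error(expected_deaths(c(0.2, 1.2)), "inside")
  # generator cross-check: sums of truth risks equal recorded expected deaths
  icu <- small_study()$icu_truth
  tr <- small_study()$truth
  e <- expected_deaths(tr$risk[tr$in_cohort & tr$source == "regA" & tr$icu_id == 1])
  expect_equal(e, icu$expected[icu$source == "regA" & icu$icu_id == 1])
})

test_that("SMR aggregation: O/E per unit, registries as ratio of sums", {
  scored <- tibble::tibble(
    source = rep("r", 300),
    icu_id = rep(1:3, each = 100),
    icu_death = rep(c(TRUE, FALSE), times = c(20, 80)) |> rep(3),
    risk = rep(c(0.1, 0.2, 0.4), each = 100))
  by_icu <- compute_smr(scored, level = "icu")
  expect_equal(by_icu$expected, c(10, 20, 40))
  expect_equal(by_icu$smr, c(2, 1, 0.5))
  by_reg <- compute_smr(scored, level = "registry")
  # ratio of sums, not mean of ICU SMRs
  expect_equal(by_reg$smr, 60 / 70)
  expect_false(isTRUE(all.equal(by_reg$smr, mean(by_icu$smr))))
  expect_equal(by_reg$expected, sum(by_icu$expected))

  # observed 20 deaths, mean risk 0.1, n = 100 -> SMR 2
  one <- compute_smr(tibble::tibble(source = "u", icu_id = 1,
                                    icu_death = rep(c(TRUE, FALSE), c(20, 80)),
                                    risk = 0.1))
  expect_equal(one$smr, 2)
})

test_that("funnel limits bracket 1, match a brute-force Poisson scan, and shrink like 1/sqrt(E)", {
  E <- c(0.5, 2, 5, 10, 25, 80, 300, 1500)
  lim <- funnel_limits(E)
  expect_true(all(lim$lower < 1 & lim$upper > 1))
  expect_true(all(diff(lim$upper) < 0))

  # independent oracle: scan the Poisson(10) pmf and interpolate the CDF
  brute_q <- function(p, E) {
    k <- 0:200
    cdf <- cumsum(dpois(k, E))
    i <- which(cdf >= p)[1]            # cdf[i] >= p > cdf[i - 1]
    f_hi <- cdf[i]
    f_lo <- if (i == 1) 0 else cdf[i - 1]
    kk <- k[i]
    (kk - 1) + (p - f_lo) / (f_hi - f_lo)
  }
  l10 <- funnel_limits(10)
  expect_equal(l10$lower, max(0, brute_q(0.025, 10)) / 10, tolerance = 1e-10)
  expect_equal(l10$upper, brute_q(0.975, 10) / 10, tolerance = 1e-10)

  # large-E normal limit
  l <- funnel_limits(10000)
  expect_lt(abs(l$upper - (1 + 1.96 / 100)) / (l$upper - 1), 0.05)
  expect_lt(abs(l$lower - (1 - 1.96 / 100)) / (1 - l$lower), 0.05)

  expect_error(funnel_limits(10, alpha = 1.2), "alpha")
  expect_error(funnel_limits(-1), "positive")
})

test_that("pooled registry funnel: degenerate at zero missingness, point is the mean of per-imputation E", {
  tr <- simulate_truth(500, seed = 88)
  scored <- tibble::tibble(source = rep(c("x", "y"), each = 250),
                           icu_id = 1, icu_death = tr$icu_death,
                           risk = tr$risk)
  pf <- pooled_funnel(list(scored, scored, scored))
  expect_equal(pf$stats$between_var, c(0, 0))
  expect_true(all(pf$stats$mi_degenerate))
  expect_equal(pf$stats$smr_lo95 <= pf$stats$smr,
               c(TRUE, TRUE))

  # perturbed copies: pooled point = mean of per-imputation expected deaths
  s2 <- scored
  s2$risk <- pmin(0.99, scored$risk * 1.1)
  s3 <- scored
  s3$risk <- scored$risk * 0.9
  pf2 <- pooled_funnel(list(scored, s2, s3))
  for (src in c("x", "y")) {
    E_j <- vapply(list(scored, s2, s3),
                  function(s) sum(s$risk[s$source == src]), 1.0)
    row <- pf2$stats[pf2$stats$source == src, ]
    expect_equal(row$expected, mean(E_j))
    # hand-worked Rubin quantities
    hand <- rubin_pool(E_j, vapply(list(scored, s2, s3), function(s) {
      sum(s$risk[s$source == src] * (1 - s$risk[s$source == src]))
    }, 1.0))
    expect_equal(row$expected_lo95, hand$ci95[1])
    expect_equal(row$expected_hi95, hand$ci95[2])
    expect_equal(row$smr, row$observed / hand$point)
  }
  # three funnel overlays, one per E variant
  expect_named(pf2$limits, c("point", "lower", "upper"))
})

test_that("demographics report: counts, medians, and half-up percentages", {
  scored <- tibble::tibble(
    source = "all_male", icu_id = rep(1:2, 5),
    age = c(30, 40, 50, 60, 70, 35, 45, 55, 65, 75),
    sex = "male", total = c(0, 5, 10, 15, 20, 2, 7, 12, 17, 22),
    icu_death = rep(c(TRUE, FALSE), 5),
    icu_los_days = seq(0.5, 5, 0.5))
  d <- demographics_table(scored)
  expect_equal(d$n_icus, 2L)
  expect_equal(d$n_patients, 10L)
  expect_equal(d$male_pct, 100)
  expect_equal(d$icu_mortality_pct, 50)
  expect_equal(d$age_median, 52.5)
  expect_equal(d$icu_los_median, 2.8)   # median of 0.5..5 is 2.75 -> half-up 2.8
})

test_that("funnel plot: centre-line unit, outlier flagging, byte-identical rendering", {
  stats <- tibble::tibble(source = c("a", "b", "c"),
                          n_admissions = c(100, 100, 100),
                          observed = c(20, 60, 20),
                          expected = c(20, 20, 7),
                          smr = c(1, 3, 20 / 7))
  out <- funnel_outliers(stats)
  expect_equal(out$status, c("in_control", "above", "above"))
  expect_true(out$lower[1] < 1 && out$upper[1] > 1)

  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  p <- plot_funnel(stats, path = f1)
  plot_funnel(stats, path = f2)
  expect_true(file.exists(f1))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_s3_class(p, "ggplot")
  expect_error(plot_funnel(stats[0, ]), "no unit")
})
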