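def <- scoring_def()

test_that("engine points match the independent threshold-chain oracle on dense grids", {
  for (v in c("temperature", "map", "heart_rate", "respiratory_rate", "ph",
              "sodium", "potassium", "creatinine", "hematocrit", "leukocytes",
              "bicarbonate")) {
    grid <- oracle_grid(v)
    engine <- score_component(v, lowest = grid, highest = grid, def)
    oracle <- vapply(grid, function(x) oracle_points(v, x), 1L)
    expect_equal(engine, oracle, info = v)
  }
  # one-sided oxygenation tables
  g <- oracle_grid("pao2")
  expect_equal(score_component("pao2", lowest = g, highest = NA, def),
               vapply(g, function(x) oracle_points("pao2", x), 1L))
  g <- oracle_grid("aado2")
  expect_equal(score_component("aado2", lowest = NA, highest = g, def),
               vapply(g, function(x) oracle_points("aado2", x), 1L))
  expect_equal(score_component("gcs", lowest = 3:15, highest = NA, def),
               15L - 3:15)
})

test_that("worst-of-extrema, absent components, and special rules behave", {
  # worst value is whichever extremum earns more points
  expect_equal(score_component("temperature", lowest = 35.0, highest = 39.5, def), 3L)
  expect_equal(score_component("temperature", lowest = 37.0, highest = 38.0, def), 0L)
  # both extrema absent -> deferred to the missingness strategy
  expect_true(is.na(score_component("sodium", NA, NA, def)))
  # one absent extremum still scores
  expect_equal(score_component("potassium", lowest = NA, highest = 6.2, def), 3L)
  # creatinine doubles under acute renal failure
  expect_equal(score_component("creatinine", 2.2, 2.2, def), 3L)
  expect_equal(score_component("creatinine", 2.2, 2.2, def,
                               acute_renal_failure = TRUE), 6L)
  # oxygenation switches bands on FiO2 at 0.5
  w <- vignette_wide(fio2 = 0.6, aado2 = 420, pao2 = NA)
  expect_equal(score_components(w, def)$oxygenation, 3L)
  w <- vignette_wide(fio2 = 0.3, pao2 = 58)
  expect_equal(score_components(w, def)$oxygenation, 3L)
  # out-of-domain values are data errors naming the variable
  expect_error(score_component("potassium", 25, 25, def),
               "potassium.*outside validated domain")
})

test_that("three hand-scored patient vignettes reproduce manual totals and risks", {
  # vignette 1: febrile septic adult, moderately deranged across the board
  w1 <- vignette_wide(temperature = 39.5, map = 120, heart_rate = 145,
                      respiratory_rate = 30, fio2 = 0.21, pao2 = 65,
                      ph = 7.30, sodium = 152, potassium = 3.2,
                      creatinine = 2.2, hematocrit = 28, leukocytes = 21,
                      gcs = 12)
  pts1 <- score_components(w1, def)
  expect_equal(unname(unlist(pts1)),
               c(3L, 2L, 3L, 1L, 1L, 2L, 1L, 1L, 3L, 2L, 2L, 3L))
  t1 <- compute_total(pts1, age = 68, severe_chronic = TRUE,
                      operative = FALSE, elective_postop = FALSE, def)
  expect_equal(t1$aps, 24L)
  expect_equal(t1$age_points, 5L)
  expect_equal(t1$chronic_points, 5L)
  expect_equal(t1$total, 34L)
  r1 <- mortality_risk(t1$total, category_weight = 0.113,
                       emergency_postop = FALSE, def)
  expect_equal(r1, plogis(-3.517 + 0.146 * 34 + 0.113), tolerance = 1e-6)
  expect_equal(round(r1, 4), 0.8264)

  # vignette 2: well elective postoperative patient with chronic disease
  w2 <- vignette_wide(temperature = 36.8, map = 92, heart_rate = 78,
                      respiratory_rate = 14, fio2 = 0.30, pao2 = 88,
                      ph = 7.42, sodium = 140, potassium = 4.1,
                      creatinine = 1.0, hematocrit = 41, leukocytes = 9,
                      gcs = 15)
  pts2 <- score_components(w2, def)
  expect_equal(sum(unlist(pts2)), 0L)
  t2 <- compute_total(pts2, age = 42, severe_chronic = TRUE,
                      operative = TRUE, elective_postop = TRUE, def)
  expect_equal(t2$total, 2L)
  r2 <- mortality_risk(t2$total, category_weight = -0.248,
                       emergency_postop = FALSE, def)
  expect_equal(r2, plogis(-3.517 + 0.146 * 2 - 0.248), tolerance = 1e-6)
  expect_equal(round(r2, 4), 0.0301)

  # vignette 3: post-arrest catastrophe with acute renal failure
  w3 <- vignette_wide(temperature = 30.5, map = 48, heart_rate = 38,
                      respiratory_rate = 52, fio2 = 0.8, aado2 = 420,
                      ph = 7.12, sodium = 118, potassium = 6.4,
                      creatinine = 3.6, hematocrit = 18, leukocytes = 0.8,
                      gcs = 4, arf = TRUE)
  pts3 <- score_components(w3, def)
  expect_equal(unname(unlist(pts3)),
               c(3L, 4L, 4L, 4L, 3L, 4L, 3L, 3L, 8L, 4L, 4L, 11L))
  t3 <- compute_total(pts3, age = 77, severe_chronic = FALSE,
                      operative = FALSE, elective_postop = FALSE, def)
  expect_equal(t3$aps, 55L)
  expect_equal(t3$total, 61L)
  r3 <- mortality_risk(t3$total, category_weight = 0.393,
                       emergency_postop = FALSE, def)
  expect_equal(r3, plogis(-3.517 + 0.146 * 61 + 0.393), tolerance = 1e-6)
  expect_equal(round(r3, 4), 0.9969)
})

test_that("chronic-health points: 2 for elective postoperative, 5 otherwise, 0 without the flag", {
  pts <- score_components(vignette_wide(temperature = 37, map = 90,
                                        heart_rate = 80, respiratory_rate = 15,
                                        fio2 = 0.21, pao2 = 90, ph = 7.4,
                                        sodium = 140, potassium = 4,
                                        creatinine = 1, hematocrit = 40,
                                        leukocytes = 8, gcs = 15), def)
  t_el <- compute_total(pts, 30, TRUE, TRUE, TRUE, def)
  t_em <- compute_total(pts, 30, TRUE, TRUE, FALSE, def)
  t_no <- compute_total(pts, 30, TRUE, FALSE, FALSE, def)
  t_ab <- compute_total(pts, 30, FALSE, FALSE, FALSE, def)
  expect_equal(t_el$chronic_points, 2L)
  expect_equal(t_em$chronic_points, 5L)
  expect_equal(t_no$chronic_points, 5L)
  expect_equal(t_ab$chronic_points, 0L)
})

test_that("risk is the stated logistic: monotone in score, 0.5 at eta = 0, emergency term additive", {
  r <- mortality_risk(0:71, category_weight = 0, emergency_postop = FALSE, def)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
  # choose the weight that zeroes eta -> risk exactly 1/2
  expect_equal(mortality_risk(20, 3.517 - 0.146 * 20, FALSE, def), 0.5)
  expect_equal(qlogis(mortality_risk(10, 0.2, TRUE, def)) -
                 qlogis(mortality_risk(10, 0.2, FALSE, def)), 0.603,
               tolerance = 1e-12)
  expect_error(mortality_risk(72, 0, FALSE, def), "\\[0, 71\\]")
  expect_error(mortality_risk(10, NA, FALSE, def), "category weight")
})

test_that("unresolved components are an error, not a silent zero", {
  w <- vignette_wide(temperature = 37, map = 90, heart_rate = 80,
                     respiratory_rate = 15, fio2 = 0.21, pao2 = 90, ph = 7.4,
                     sodium = 140, creatinine = 1, hematocrit = 40,
                     leukocytes = 8, gcs = 15)   # potassium missing
  pts <- score_components(w, def)
  expect_error(compute_total(pts, 50, FALSE, FALSE, FALSE, def),
               "unresolved.*potassium")
})

test_that("scoring definition validation rejects overlapping and disordered bands", {
  bad <- def
  bad$physiology$sodium$lo[3] <- bad$physiology$sodium$hi[2] - 1
  expect_error(validate_scoring_definition(bad), "overlapping")
  bad2 <- def
  bad2$physiology$map$points[2] <- 5L   # points no longer increase outward
  expect_error(validate_scoring_definition(bad2), "increase away from normal")
})

test_that("diagnosis maps: lookup, unmapped marker, duplicate rejection, two-stage composition", {
  m <- diagnosis_map(tibble::tibble(source_code = c(1, 2),
                                    category = c("nonop_sepsis", "nonop_copd")))
  got <- map_reason(c(1, 2, 99), m, def)
  expect_equal(got$category, c("nonop_sepsis", "nonop_copd", NA))
  expect_equal(got$weight, c(0.113, -0.367, NA))
  expect_true(is.na(got$weight[3]))   # unmapped -> marker, never a default

  expect_error(diagnosis_map(tibble::tibble(
    source_code = c(1, 1), category = c("nonop_sepsis", "nonop_copd"))),
    "multiple categories")

  # two-stage map equals the composition of its stages
  inter <- diagnosis_map(tibble::tibble(source_code = c(10, 11),
                                        category = c("nonop_sepsis",
                                                     "postop_gi_neoplasm")))
  two <- diagnosis_map(tibble::tibble(source_code = c(501, 502, 503),
                                      intermediate_code = c(10, 11, 77)),
                       via = inter)
  got2 <- map_reason(c(501, 502, 503), two, def)
  lk1 <- c(`501` = 10, `502` = 11, `503` = 77)
  manual <- inter$entries$category[match(lk1, inter$entries$source_code)]
  expect_equal(got2$category, unname(manual))
  expect_true(is.na(got2$category[3]))

  # shipped dialect-B map chains through the dialect-A vocabulary
  mb <- dialect_diagnosis_map("B")
  ma <- dialect_diagnosis_map("A")
  expect_setequal(unique(mb$entries$category), unique(ma$entries$category))
})
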