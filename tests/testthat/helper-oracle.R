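# Independent brute-force scoring oracle: explicit threshold chains
# transcribed directly from the published scoring sheet, written without
# reference to the engine's band tables. Values in the printed gaps
# between bands take the adjacent band with the higher point value, and
# bands printed as strict inequalities keep their strict boundary.
oracle_points <- function(variable, v) {
  if (is.na(v)) return(NA_integer_)
  pts <- switch(variable,
    temperature = if (v > 40.9) 4 else if (v > 38.9) 3 else if (v > 38.4) 1
      else if (v >= 36) 0 else if (v >= 34) 1 else if (v >= 32) 2
      else if (v >= 30) 3 else 4,
    map = if (v > 159) 4 else if (v > 129) 3 else if (v > 109) 2
      else if (v >= 70) 0 else if (v >= 50) 2 else 4,
    heart_rate = if (v > 179) 4 else if (v > 139) 3 else if (v > 109) 2
      else if (v >= 70) 0 else if (v >= 55) 2 else if (v >= 40) 3 else 4,
    respiratory_rate = if (v > 49) 4 else if (v > 34) 3 else if (v > 24) 1
      else if (v >= 12) 0 else if (v >= 10) 1 else if (v >= 6) 2 else 4,
    pao2 = if (v >= 70.1) 0 else if (v >= 61) 1 else if (v >= 55) 3 else 4,
    aado2 = if (v > 499) 4 else if (v > 349) 3 else if (v > 199.9) 2 else 0,
    ph = if (v > 7.69) 4 else if (v > 7.59) 3 else if (v > 7.49) 1
      else if (v >= 7.33) 0 else if (v >= 7.25) 2 else if (v >= 7.15) 3 else 4,
    sodium = if (v > 179) 4 else if (v > 159) 3 else if (v > 154) 2
      else if (v > 149) 1 else if (v >= 130) 0 else if (v >= 120) 2
      else if (v >= 111) 3 else 4,
    potassium = if (v > 6.9) 4 else if (v > 5.9) 3 else if (v > 5.4) 1
      else if (v >= 3.5) 0 else if (v >= 3) 1 else if (v >= 2.5) 2 else 4,
    creatinine = if (v > 3.4) 4 else if (v > 1.9) 3 else if (v > 1.4) 2
      else if (v >= 0.6) 0 else 2,
    hematocrit = if (v > 59.9) 4 else if (v > 49.9) 2 else if (v > 45.9) 1
      else if (v >= 30) 0 else if (v >= 20) 2 else 4,
    leukocytes = if (v > 39.9) 4 else if (v > 19.9) 2 else if (v > 14.9) 1
      else if (v >= 3) 0 else if (v >= 1) 2 else 4,
    bicarbonate = if (v > 51.9) 4 else if (v > 40.9) 3 else if (v > 31.9) 1
      else if (v >= 22) 0 else if (v >= 18) 2 else if (v >= 15) 3 else 4,
    gcs = 15 - v,
    stop("oracle: unknown variable ", variable))
  as.integer(pts)
}

oracle_age_points <- function(age) {
  as.integer(if (age <= 44) 0 else if (age <= 54) 2 else if (age <= 64) 3
             else if (age <= 74) 5 else 6)
}

# dense value grid per variable: regular sweep plus band edges and
# just-off-edge values (the deterministic tie-break region)
oracle_grid <- function(variable) {
  ranges <- list(
    temperature = c(26, 45), map = c(20, 250), heart_rate = c(10, 300),
    respiratory_rate = c(0, 100), pao2 = c(20, 400), aado2 = c(0, 800),
    ph = c(6.8, 7.95), sodium = c(90, 210), potassium = c(1, 11),
    creatinine = c(0.1, 12), hematocrit = c(6, 78), leukocytes = c(0, 250),
    bicarbonate = c(2, 75), gcs = c(3, 15))
  r <- ranges[[variable]]
  edges <- list(
    temperature = c(29.9, 30, 32, 34, 36, 38.4, 38.5, 38.9, 39, 40.9, 41),
    map = c(49, 50, 70, 109, 110, 129, 130, 159, 160),
    heart_rate = c(39, 40, 55, 70, 109, 110, 139, 140, 179, 180),
    respiratory_rate = c(5, 6, 10, 12, 24, 25, 34, 35, 49, 50),
    pao2 = c(54.9, 55, 60, 61, 70, 70.1),
    aado2 = c(199.9, 200, 349, 350, 499, 500),
    ph = c(7.14, 7.15, 7.25, 7.32, 7.33, 7.49, 7.5, 7.59, 7.6, 7.69, 7.7),
    sodium = c(110, 111, 120, 130, 149, 150, 154, 155, 159, 160, 179, 180),
    potassium = c(2.4, 2.5, 3, 3.4, 3.5, 5.4, 5.5, 5.9, 6, 6.9, 7),
    creatinine = c(0.5, 0.6, 1.4, 1.5, 1.9, 2, 3.4, 3.5),
    hematocrit = c(19.9, 20, 30, 45.9, 46, 49.9, 50, 59.9, 60),
    leukocytes = c(0.9, 1, 3, 14.9, 15, 19.9, 20, 39.9, 40),
    bicarbonate = c(14.9, 15, 18, 22, 31.9, 32, 40.9, 41, 51.9, 52),
    gcs = 3:15)[[variable]]
  if (variable == "gcs") return(3:15)
  sort(unique(round(c(seq(r[1], r[2], length.out = 400), edges,
                      edges - 0.013, edges + 0.013), 4)))
}
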