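# Independent oracles: deliberately naive, self-contained implementations
# used only to check the package's results.

# Plain cyclic coordinate descent for the lasso objective
# (1/(2n)) * RSS + lambda * ||beta||_1 with unpenalized intercept.
# No active sets, no warm starts, fixed sweep count.
oracle_lasso <- function(x, y, lambda, sweeps = 4000) {
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  n <- nrow(x); p <- ncol(x)
  b <- rep(0, p)
  v <- colSums(xc^2) / n
  r <- y - ym
  for (it in seq_len(sweeps)) {
    for (j in seq_len(p)) {
      if (v[j] == 0) next
      u <- sum(xc[, j] * r) / n + v[j] * b[j]
      bn <- sign(u) * max(abs(u) - lambda, 0) / v[j]
      if (bn != b[j]) {
        r <- r - (bn - b[j]) * xc[, j]
        b[j] <- bn
      }
    }
  }
  list(beta = b, intercept = ym - sum(xm * b))
}

# The four published race-sex pooled cohort equations written out longhand,
# one expression per group (a spreadsheet-style transcription).
oracle_pce <- function(age, sex, black, tc, hdl, sbp, treated, smoker,
                       diabetes) {
  la <- log(age); lt <- log(tc); lh <- log(hdl); ls <- log(sbp)
  if (!black && sex == "male") {
    s <- 12.344 * la + 11.853 * lt - 2.664 * la * lt - 7.990 * lh +
      1.769 * la * lh +
      (if (treated) 1.797 * ls else 1.764 * ls) +
      (if (smoker) 7.837 - 1.795 * la else 0) +
      (if (diabetes) 0.658 else 0)
    return(1 - 0.9144 ^ exp(s - 61.18))
  }
  if (!black && sex == "female") {
    s <- -29.799 * la + 4.884 * la^2 + 13.540 * lt - 3.114 * la * lt -
      13.578 * lh + 3.149 * la * lh +
      (if (treated) 2.019 * ls else 1.957 * ls) +
      (if (smoker) 7.574 - 1.665 * la else 0) +
      (if (diabetes) 0.661 else 0)
    return(1 - 0.9665 ^ exp(s + 29.18))
  }
  if (black && sex == "male") {
    s <- 2.469 * la + 0.302 * lt - 0.307 * lh +
      (if (treated) 1.916 * ls else 1.809 * ls) +
      (if (smoker) 0.549 else 0) +
      (if (diabetes) 0.645 else 0)
    return(1 - 0.8954 ^ exp(s - 19.54))
  }
  s <- 17.114 * la + 0.940 * lt - 18.920 * lh + 4.475 * la * lh +
    (if (treated) 29.291 * ls - 6.432 * la * ls
     else 27.820 * ls - 6.087 * la * ls) +
    (if (smoker) 0.691 else 0) +
    (if (diabetes) 0.874 else 0)
  1 - 0.9533 ^ exp(s - 86.61)
}

# Blom normal scores straight from the defining formula.
oracle_blom <- function(x) {
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

# A diet questionnaire row hitting every component's best band, with
# overridable fields.
max_diet_row <- function(...) {
  row <- data.frame(
    sex = "female", veg_fruit_per_day = 5, whole_grains_per_day = 3,
    oily_fish_per_week = 1, lean_meat_per_week = 3,
    nonmeat_protein_per_week = 3, sugared_bev_per_day = 0,
    high_fat_meat_per_week = 0, fast_food_per_week = 0,
    fermented_dairy_per_day = 2, alcohol_days_per_week = 3,
    alcohol_drinks_per_day = 1)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# ... and every component's worst band.
min_diet_row <- function(...) {
  max_diet_row(veg_fruit_per_day = 0, whole_grains_per_day = 0,
               oily_fish_per_week = 0, lean_meat_per_week = 0,
               nonmeat_protein_per_week = 0, sugared_bev_per_day = 4,
               high_fat_meat_per_week = 3, fast_food_per_week = 1,
               fermented_dairy_per_day = 0, alcohol_days_per_week = 0,
               alcohol_drinks_per_day = 0, ...)
}

# A clinical profile that triggers a chosen subset of the five MetS
# criteria (and no medication overrides).
mets_profile <- function(central = FALSE, tg = FALSE, hdl = FALSE,
                         bp = FALSE, glucose = FALSE, sex = "male") {
  data.frame(
    sex = sex,
    waist_cm = if (central) 110 else 80,
    triglycerides_mg_dl = if (tg) 180 else 100,
    hdl_mg_dl = if (hdl) 35 else 60,
    sbp_mmhg = if (bp) 140 else 115,
    dbp_mmhg = if (bp) 90 else 70,
    glucose_mg_dl = if (glucose) 110 else 90,
    on_tg_treatment = FALSE, on_hdl_treatment = FALSE,
    on_htn_treatment_with_dx = FALSE, on_glucose_treatment = FALSE)
}

# A random covariate table inside the risk calculator's validity windows.
random_risk_grid <- function(n, seed = 31) {
  set.seed(seed)
  data.frame(
    age = runif(n, 40, 79),
    sex = sample(c("male", "female"), n, TRUE),
    race_group = sample(c("white_other", "african_american"), n, TRUE),
    total_chol_mg_dl = runif(n, 130, 320),
    hdl_mg_dl = runif(n, 20, 100),
    sbp_mmhg = runif(n, 90, 200),
    treated_htn = sample(c(TRUE, FALSE), n, TRUE),
    smoker = sample(c(TRUE, FALSE), n, TRUE),
    diabetes = sample(c(TRUE, FALSE), n, TRUE))
}
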