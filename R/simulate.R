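# Synthetic two-wave cohort generator. A single latent diet-quality factor
# D drives (a) the questionnaire responses through a 21-step threshold
# ladder whose cut points are placed at quantiles of a discretized normal
# target for the HEI total, (b) a planted subset of lipid species through
# geometrically decaying loadings scaled to a requested population
# signature-HEI correlation, and (c) the cardiometabolic biomarkers through
# a shared metabolic factor plus explicit per-biomarker effects. Ground
# truth is kept in a sidecar never read by the pipeline.

.hei_step_order <- function() {
  c("oily_fish", "fast_food", "alcohol", "fermented_dairy", "veg_fruit",
    "high_fat_meat", "whole_grains", "sugared_bev", "lean_meat",
    "nonmeat_protein", "veg_fruit", "oily_fish", "alcohol", "whole_grains",
    "fermented_dairy", "high_fat_meat", "sugared_bev", "lean_meat",
    "nonmeat_protein", "fast_food", "veg_fruit")
}

# Thresholds on the latent scale for the 21 band steps, placed so that the
# marginal distribution of the generated HEI total matches a discretized
# N(hei_mean, hei_sd) on {0, 0.5, ..., 11} exactly (in expectation).
.hei_step_ladder <- function(hei_mean, hei_sd) {
  ord <- .hei_step_order()
  # step sizes: every step is +0.5 except the third veg_fruit step (+1)
  delta <- rep(0.5, length(ord))
  delta[ord == "veg_fruit"][3] <- 1
  levels_grid <- seq(0, 11, by = 0.5)
  p <- stats::dnorm(levels_grid, hei_mean, hei_sd)
  p <- p / sum(p)
  G <- cumsum(p)
  level_before <- cumsum(c(0, delta[-length(delta)]))
  t_k <- stats::qnorm(G[match(level_before, levels_grid)])
  data.frame(component = ord, step = stats::ave(seq_along(ord), ord,
                                                FUN = seq_along),
             delta = delta, level_before = level_before, threshold = t_k)
}

# Map a component band index (0 = worst) to a questionnaire intake that
# score_hei() will place back in the same band.
.draw_intake <- function(component, band, sex) {
  n <- length(band)
  pick <- function(lo, hi) if (lo == hi) rep(lo, n) else sample(lo:hi, n, TRUE)
  runifv <- function(lo, hi) stats::runif(n, lo, hi)
  out <- switch(component,
    veg_fruit = ifelse(band == 0, 0, ifelse(band == 1, pick(1, 2),
                ifelse(band == 2, pick(3, 4), pick(5, 8)))),
    whole_grains = ifelse(band == 0, 0, ifelse(band == 1, pick(1, 2), pick(3, 5))),
    oily_fish = ifelse(band == 0, 0, ifelse(band == 1, runifv(0.3, 0.9),
                round(runifv(1, 3), 1))),
    lean_meat = ifelse(band == 0, 0, ifelse(band == 1, pick(1, 2), pick(3, 5))),
    nonmeat_protein = ifelse(band == 0, runifv(0, 0.9),
                      ifelse(band == 1, pick(1, 2), pick(3, 6))),
    sugared_bev = ifelse(band == 0, pick(4, 7), ifelse(band == 1, pick(1, 3), 0)),
    high_fat_meat = ifelse(band == 0, pick(3, 6), ifelse(band == 1, pick(1, 2), 0)),
    fast_food = ifelse(band == 0, round(runifv(1, 4), 1),
                ifelse(band == 1, round(runifv(0.1, 0.9), 2), 0)),
    fermented_dairy = {
      v <- numeric(n)
      b0 <- band == 0
      high0 <- b0 & stats::runif(n) < 0.1      # the ">= 5" arm of the 0 band
      v[b0] <- runifv(0, 0.95)[b0]
      v[high0] <- runifv(5, 6)[high0]
      b1 <- band == 1
      hi1 <- b1 & stats::runif(n) < 0.5
      v[b1] <- runifv(1, 1.95)[b1]
      v[hi1] <- runifv(4, 4.95)[hi1]
      v[band == 2] <- runifv(2, 3.95)[band == 2]
      round(v, 2)
    },
    stop("unknown component ", component))
  round(out, 2)
}

.draw_alcohol <- function(band, sex) {
  n <- length(band)
  limit <- ifelse(sex == "male", 2, 1)
  days <- integer(n); drinks <- numeric(n)
  b0 <- band == 0
  over <- b0 & stats::runif(n) < 0.15          # over-limit drinkers
  days[b0] <- 0; drinks[b0] <- 0
  days[over] <- sample(1:7, sum(over), TRUE)
  drinks[over] <- limit[over] + sample(1:3, sum(over), TRUE)
  b1 <- band == 1
  days[b1] <- sample(1:2, sum(b1), TRUE)
  drinks[b1] <- ifelse(limit[b1] == 2, sample(1:2, sum(b1), TRUE), 1)
  b2 <- band == 2
  days[b2] <- sample(3:7, sum(b2), TRUE)
  drinks[b2] <- ifelse(limit[b2] == 2, sample(1:2, sum(b2), TRUE), 1)
  list(days = days, drinks = drinks)
}

# Exact P(at least 3 of 5 criteria | per-criterion probabilities), by the
# Poisson-binomial recursion, vectorized over subjects (q: n x 5).
.p_ge3_of5 <- function(q) {
  n <- nrow(q)
  dp <- matrix(0, n, 6)
  dp[, 1] <- 1
  for (c in 1:5) {
    nd <- matrix(0, n, 6)
    for (k in 1:(c + 1)) {
      nd[, k] <- dp[, k] * (1 - q[, c]) +
        (if (k > 1) dp[, k - 1] * q[, c] else 0)
    }
    dp <- nd
  }
  rowSums(dp[, 4:6, drop = FALSE])
}

#' Generate a synthetic two-wave cohort with planted effects
#'
#' Emulates the statistical structure the analysis pipeline assumes: a
#' training wave ("core") and a testing wave ("refresher"); questionnaire
#' responses whose healthy-eating-index total has a chosen mean and spread
#' and tracks a latent diet-quality factor D at r > 0.9; a lipid panel in
#' which a planted subset of species loads on D with geometrically decaying
#' loadings scaled so the population correlation between the best linear
#' lipid combination and the HEI equals `diet_lipid_coupling`; biomarkers
#' carrying planted standardized effects of D with the sign structure seen
#' in observational diet-lipidome studies (HDL-c positive; insulin,
#' HOMA-IR, IL-6, CRP, BMI negative); and metabolic-syndrome component
#' fields calibrated (by an exact conditional Poisson-binomial root solve)
#' so the classified MetS prevalence is close to `mets_target_prevalence`.
#' Ground truth (latent factor, loadings, planted effects) is returned in a
#' `truth` element that the pipeline never reads.
#'
#' @param n_train,n_test Wave sizes (defaults 1200 / 850).
#' @param n_lipids Total lipid species (default 400).
#' @param n_signal_lipids Planted diet-responsive species (default 57).
#' @param diet_lipid_coupling Target population correlation rho* in [0, 1)
#'   between the best linear lipid combination and the HEI (default 0.4).
#' @param biomarker_effects Named standardized effects of D on the
#'   log-scale linear predictors of the non-criterion biomarkers.
#' @param mets_target_prevalence Target MetS prevalence (default 0.37).
#' @param hei_mean,hei_sd Target HEI total mean and SD (defaults 5.8, 1.5).
#' @param lod_high_species Fraction of noise species given heavy
#'   left-censoring (below-LOD fractions 0.25-0.6, hence dropped by the 20%
#'   filter); all other species get light censoring (0-8%).
#' @param missing_diet_rate Per-subject probability of one missing diet
#'   field (default 0: every subject scorable).
#' @param loading_decay Geometric ratio of the planted loadings across the
#'   signal species (default 0.5: a few dominant species over a long tail;
#'   1 plants equal loadings).
#' @param seed Integer seed; mandatory, fully determines the bundle.
#' @return An object of class `cohort_bundle`: list with `demographics`,
#'   `diet`, `clinical`, `lipids` (a [lipid_matrix()]), `truth`, `config`.
#' @export
simulate_cohort <- function(n_train = 1200, n_test = 850, n_lipids = 400,
                            n_signal_lipids = 57, diet_lipid_coupling = 0.4,
                            biomarker_effects = c(insulin = -0.20,
                                                  il6 = -0.15, crp = -0.15),
                            mets_target_prevalence = 0.37,
                            hei_mean = 5.8, hei_sd = 1.5,
                            lod_high_species = 0.15,
                            missing_diet_rate = 0, loading_decay = 0.5,
                            seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_train > 0, n_test >= 0, n_lipids >= n_signal_lipids,
            diet_lipid_coupling >= 0, diet_lipid_coupling < 1)
  set.seed(as.integer(seed))
  n <- n_train + n_test
  id <- sprintf("S%04d", seq_len(n))
  wave <- c(rep("core", n_train), rep("refresher", n_test))

  ## --- demographics -------------------------------------------------------
  sex <- sample(c("male", "female"), n, TRUE, prob = c(0.45, 0.55))
  race <- sample(c("white", "non_white"), n, TRUE, prob = c(0.75, 0.25))
  race_group <- ifelse(race == "white", "white_other",
                       ifelse(stats::runif(n) < 0.7, "african_american",
                              "white_other"))
  education <- sample(c("hs_or_less", "college", "postgraduate"), n, TRUE,
                      prob = c(0.24, 0.52, 0.24))
  smoking <- sample(c("never", "former", "current"), n, TRUE,
                    prob = c(0.47, 0.37, 0.16))
  age <- pmin(90, pmax(35, round(stats::rnorm(n, 55, 12.5))))
  age_z <- (age - 55) / 12.5

  ## --- latent diet quality D ---------------------------------------------
  shifts <- 0.12 * (sex == "female") + 0.15 * (race == "white") +
    0.10 * age_z +
    c(hs_or_less = -0.18, college = 0, postgraduate = 0.18)[education] +
    c(never = 0.08, former = 0.02, current = -0.25)[smoking] +
    ifelse(wave == "core", -0.14, 0.14)
  D <- shifts + stats::rnorm(n) * sqrt(max(0.3, 1 - stats::var(shifts)))
  D <- (D - mean(D)) / stats::sd(D)
  physical_activity <- as.integer(stats::runif(n) <
                                    stats::plogis(0.4 + 0.35 * D))

  demographics <- data.frame(subject_id = id, wave = wave, sex = sex,
                             race = race, race_group = race_group, age = age,
                             education = education, smoking = smoking,
                             physical_activity = physical_activity)

  ## --- diet questionnaire via the threshold ladder ------------------------
  w_comp <- 0.97
  ladder <- .hei_step_ladder(hei_mean, hei_sd)
  diet <- data.frame(subject_id = id, sex = sex)
  bands <- list()
  for (comp in hei_components()) {
    thr <- ladder$threshold[ladder$component == comp]
    z_c <- w_comp * D + sqrt(1 - w_comp^2) * stats::rnorm(n)
    bands[[comp]] <- rowSums(outer(z_c, thr, `>`))
  }
  diet$veg_fruit_per_day <- .draw_intake("veg_fruit", bands$veg_fruit, sex)
  diet$whole_grains_per_day <- .draw_intake("whole_grains", bands$whole_grains, sex)
  diet$oily_fish_per_week <- .draw_intake("oily_fish", bands$oily_fish, sex)
  diet$lean_meat_per_week <- .draw_intake("lean_meat", bands$lean_meat, sex)
  diet$nonmeat_protein_per_week <-
    .draw_intake("nonmeat_protein", bands$nonmeat_protein, sex)
  diet$sugared_bev_per_day <- .draw_intake("sugared_bev", bands$sugared_bev, sex)
  diet$high_fat_meat_per_week <-
    .draw_intake("high_fat_meat", bands$high_fat_meat, sex)
  diet$fast_food_per_week <- .draw_intake("fast_food", bands$fast_food, sex)
  diet$fermented_dairy_per_day <-
    .draw_intake("fermented_dairy", bands$fermented_dairy, sex)
  alc <- .draw_alcohol(bands$alcohol, sex)
  diet$alcohol_days_per_week <- alc$days
  diet$alcohol_drinks_per_day <- alc$drinks
  if (missing_diet_rate > 0) {
    hit <- which(stats::runif(n) < missing_diet_rate)
    fields <- setdiff(hei_diet_columns(), "sex")
    for (i in hit) diet[i, sample(fields, 1)] <- NA
  }

  # realized diet-quality/HEI correlation, needed to scale the lipid
  # loadings (signature ~ D ~ HEI chain)
  hs <- score_hei(diet, allow_partial = TRUE)
  ok <- hs$n_missing == 0
  r_dh <- stats::cor(D[ok], hs$total[ok])

  ## --- lipid panel ---------------------------------------------------------
  rho <- diet_lipid_coupling
  if (rho > 0 && rho >= 0.995 * r_dh) {
    stop(sprintf(paste0("infeasible diet_lipid_coupling %.3f: the lipidome ",
                        "can track the HEI at most at r(D, HEI) = %.3f"),
                 rho, r_dh))
  }
  loadings <- rep(0, n_lipids)
  signal_idx <- sample.int(n_lipids, n_signal_lipids)
  if (rho > 0) {
    R <- rho / r_dh
    s2 <- R^2 / (1 - R^2)
    # geometric decay: a handful of dominant species over a long tail,
    # mirroring the coefficient profile such signatures show in practice;
    # loading_decay = 1 plants equal loadings across the signal species
    decay <- loading_decay ^ (0:(n_signal_lipids - 1))
    a <- decay * sqrt(s2 / sum(decay^2))
    signs <- ifelse(stats::runif(n_signal_lipids) < 0.6, 1, -1)
    loadings[signal_idx] <- a * signs
  }
  lipid_lat <- outer(D, loadings) +
    matrix(stats::rnorm(n * n_lipids), n, n_lipids)
  base <- exp(stats::rnorm(n_lipids, 3, 1.2))
  conc <- sweep(exp(0.5 * lipid_lat), 2, base, `*`)

  classes <- sample(c("TG", "PC", "PE-O", "LPC", "SM", "CE", "DG", "PE",
                      "FFA", "CER"), n_lipids, TRUE,
                    prob = c(0.23, 0.19, 0.11, 0.07, 0.09, 0.08, 0.06,
                             0.08, 0.05, 0.04))
  fa <- paste0(sample(c(14, 16, 18, 20, 22), n_lipids, TRUE), ":",
               sample(0:6, n_lipids, TRUE))
  species <- make.unique(paste0(classes, "(", fa, ")"), sep = "_")
  colnames(conc) <- species
  rownames(conc) <- id

  n_noise <- n_lipids - n_signal_lipids
  heavy <- sample(setdiff(seq_len(n_lipids), signal_idx),
                  round(lod_high_species * n_noise))
  lod_frac <- stats::runif(n_lipids, 0, 0.03)
  lod_frac[heavy] <- stats::runif(length(heavy), 0.25, 0.6)
  below_lod <- matrix(FALSE, n, n_lipids, dimnames = dimnames(conc))
  for (j in seq_len(n_lipids)) {
    k <- floor(lod_frac[j] * n)
    if (k > 0) {
      ord <- order(conc[, j])[seq_len(k)]
      below_lod[ord, j] <- TRUE
      conc[ord, j] <- max(conc[ord, j])  # censor at the detection limit
    }
  }
  species_meta <- data.frame(species = species, class = classes,
                             fa_composition = fa)
  lipids <- lipid_matrix(conc, below_lod, species_meta)

  ## --- clinical / metabolic syndrome --------------------------------------
  kappa_age <- 0.25; kappa_d <- 0.18
  M <- sqrt(1 - kappa_age^2 - kappa_d^2) * stats::rnorm(n) +
    kappa_age * age_z - kappa_d * D
  lam <- 0.65
  rates <- c(0.45, 0.32, 0.30, 0.42, 0.40)  # adiposity, TG, HDL, BP, glucose
  tau <- stats::qnorm(1 - rates)
  prev_at <- function(delta) {
    q <- stats::pnorm((lam * M - rep(tau + delta, each = n)) /
                        sqrt(1 - lam^2))
    dim(q) <- c(n, 5)
    mean(.p_ge3_of5(q)) - mets_target_prevalence
  }
  delta <- stats::uniroot(prev_at, c(-3, 3))$root
  taud <- tau + delta
  zc <- sapply(1:5, function(c) lam * M + sqrt(1 - lam^2) * stats::rnorm(n))
  exc <- sweep(zc, 2, taud)               # criterion excess: > 0 => abnormal

  waist_cut <- ifelse(sex == "male", 102, 88)
  hdl_cut <- ifelse(sex == "male", 40, 50)
  waist <- round(waist_cut * exp(0.13 * exc[, 1]), 1)
  tg <- round(150 * exp(0.55 * exc[, 2]), 1)
  hdl <- round(hdl_cut * exp(-0.22 * exc[, 3]), 1)
  sbp <- round(130 * exp(0.105 * exc[, 4]), 1)
  dbp <- round(0.5 * sbp + 8 + stats::rnorm(n, 0, 3.5), 1)
  glucose <- round(100 * exp(0.10 * exc[, 5]), 1)

  b_adip <- exc[, 1]
  bmi <- round(28.8 * exp(0.16 * (0.8 * b_adip + 0.6 * stats::rnorm(n)) /
                            sqrt(0.8^2 + 0.6^2)), 1)
  eff <- function(nm) if (nm %in% names(biomarker_effects))
    biomarker_effects[[nm]] else 0
  mk_eta <- function(b_ad, b_glu, beta_d) {
    resid <- sqrt(max(0.05, 1 - b_ad^2 - b_glu^2 - beta_d^2))
    b_ad * b_adip + b_glu * exc[, 5] + beta_d * D + resid * stats::rnorm(n)
  }
  insulin <- round(9.5 * exp(0.55 * mk_eta(0.5, 0.3, eff("insulin"))), 1)
  il6 <- round(2.6 * exp(0.65 * mk_eta(0.4, 0, eff("il6"))), 2)
  crp <- round(1.6 * exp(1.0 * mk_eta(0.4, 0, eff("crp"))), 2)
  homa_ir <- round(glucose * insulin / 405, 2)
  hba1c <- round(5.55 + 0.36 * exc[, 5] + stats::rnorm(n, 0, 0.25), 2)
  ldl <- round(pmax(40, stats::rnorm(n, 112, 28)), 1)
  total_chol <- round(ldl + hdl + tg / 5, 1)

  rx <- function(ind, p_pos, p_neg) {
    ifelse(ind, stats::runif(n) < p_pos, stats::runif(n) < p_neg)
  }
  on_tg <- rx(exc[, 2] > 0, 0.15, 0.01)
  on_hdl <- rx(exc[, 3] > 0, 0.05, 0.005)
  on_htn <- rx(exc[, 4] > 0, 0.35, 0.02)
  on_glu <- rx(exc[, 5] > 0, 0.20, 0.01)

  clinical <- data.frame(
    subject_id = id, sex = sex, waist_cm = waist, bmi = bmi,
    sbp_mmhg = sbp, dbp_mmhg = dbp, triglycerides_mg_dl = tg,
    hdl_mg_dl = hdl, ldl_mg_dl = ldl, total_chol_mg_dl = total_chol,
    glucose_mg_dl = glucose, insulin_uiu_ml = insulin, hba1c_pct = hba1c,
    homa_ir = homa_ir, il6_pg_ml = il6, crp_mg_l = crp,
    on_tg_treatment = on_tg, on_hdl_treatment = on_hdl,
    on_htn_treatment_with_dx = on_htn, on_glucose_treatment = on_glu)

  truth <- list(
    subjects = data.frame(subject_id = id, wave = wave, diet_quality = D,
                          metabolic_factor = M),
    lipid_loadings = data.frame(species = species, loading = loadings,
                                signal = seq_len(n_lipids) %in% signal_idx),
    biomarker_effects = biomarker_effects,
    r_diet_hei = r_dh, mets_threshold_shift = delta)

  structure(list(demographics = demographics, diet = diet,
                 clinical = clinical, lipids = lipids, truth = truth,
                 config = list(n_train = n_train, n_test = n_test,
                               n_lipids = n_lipids,
                               n_signal_lipids = n_signal_lipids,
                               diet_lipid_coupling = diet_lipid_coupling,
                               mets_target_prevalence = mets_target_prevalence,
                               hei_mean = hei_mean, hei_sd = hei_sd,
                               lod_high_species = lod_high_species,
                               missing_diet_rate = missing_diet_rate,
                               seed = as.integer(seed))),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle: ", nrow(x$demographics), " subjects (",
      x$config$n_train, " core / ", x$config$n_test, " refresher), ",
      ncol(x$lipids$values), " lipid species\n", sep = "")
  cat("  planted signature-HEI coupling rho* = ",
      x$config$diet_lipid_coupling, ", seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a cohort bundle to a directory of delimited tables
#'
#' Plain CSV throughout; ground truth is segregated under `truth/` so the
#' analysis pipeline can be pointed at the directory without seeing it.
#'
#' @param bundle A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(bundle$demographics, "demographics.csv")
  wr(bundle$diet, "diet.csv")
  wr(bundle$clinical, "clinical.csv")
  lv <- data.frame(subject_id = rownames(bundle$lipids$values),
                   bundle$lipids$values, check.names = FALSE)
  wr(lv, "lipids.csv")
  lm_ <- data.frame(subject_id = rownames(bundle$lipids$values),
                    bundle$lipids$below_lod * 1L, check.names = FALSE)
  wr(lm_, "lipid_lod.csv")
  wr(bundle$lipids$species_meta, "lipid_species.csv")
  wr(bundle$truth$subjects, "truth/subjects.csv")
  wr(bundle$truth$lipid_loadings, "truth/lipid_loadings.csv")
  cfg <- bundle$config
  wr(data.frame(key = names(cfg), value = unlist(cfg)), "truth/config.csv")
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the bundle tables.
#' @param truth Also load the ground-truth sidecar (default TRUE when
#'   present).
#' @return A `cohort_bundle`.
#' @export
read_cohort <- function(dir, truth = TRUE) {
  rd <- function(f, ...) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing bundle file: ", f)
    utils::read.csv(path, check.names = FALSE, ...)
  }
  demographics <- rd("demographics.csv")
  diet <- rd("diet.csv")
  clinical <- rd("clinical.csv")
  lv <- rd("lipids.csv")
  lm_ <- rd("lipid_lod.csv")
  meta <- rd("lipid_species.csv")
  vals <- as.matrix(lv[, -1, drop = FALSE])
  rownames(vals) <- lv[[1]]
  mask <- as.matrix(lm_[, -1, drop = FALSE]) == 1
  rownames(mask) <- lm_[[1]]
  lipids <- lipid_matrix(vals, mask, meta)
  tr <- NULL
  cfg <- list()
  if (truth && file.exists(file.path(dir, "truth", "subjects.csv"))) {
    tr <- list(subjects = rd("truth/subjects.csv"),
               lipid_loadings = rd("truth/lipid_loadings.csv"))
    cfg_df <- rd("truth/config.csv")
    cfg <- as.list(utils::type.convert(stats::setNames(cfg_df$value,
                                                       cfg_df$key),
                                       as.is = TRUE))
  }
  if (!length(cfg)) {
    cfg <- list(n_train = sum(demographics$wave == "core"),
                n_test = sum(demographics$wave == "refresher"),
                n_lipids = ncol(vals))
  }
  structure(list(demographics = demographics, diet = diet,
                 clinical = clinical, lipids = lipids, truth = tr,
                 config = cfg),
            class = "cohort_bundle")
}
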