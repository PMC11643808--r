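#' Derive pooled-cohort-equation inputs from demographics and clinical data
#'
#' Builds the risk-calculator input table: maps race to the two published
#' coefficient groups, takes the hypertension-treatment flag, flags current
#' smokers, and derives diabetes from glucose-lowering treatment or
#' HbA1c >= 6.5% (no explicit diagnosis field is assumed).
#'
#' @param demographics Table with `subject_id`, `sex`, `race_group` (or
#'   `race`), `age`, `smoking`.
#' @param clinical Table with `subject_id`, `total_chol_mg_dl`,
#'   `hdl_mg_dl`, `sbp_mmhg`, `on_htn_treatment_with_dx`,
#'   `on_glucose_treatment`, `hba1c_pct`.
#' @return Data frame ready for [cvd_eligibility()] and [pce_risk()].
#' @export
prepare_risk_inputs <- function(demographics, clinical) {
  d <- merge(demographics, clinical, by = "subject_id",
             suffixes = c("", ".clin"))
  race_group <- if ("race_group" %in% names(d)) d$race_group else
    ifelse(d$race == "white", "white_other", "african_american")
  data.frame(
    subject_id = d$subject_id,
    age = d$age,
    sex = d$sex,
    race_group = race_group,
    total_chol_mg_dl = d$total_chol_mg_dl,
    hdl_mg_dl = d$hdl_mg_dl,
    sbp_mmhg = d$sbp_mmhg,
    treated_htn = as.logical(d$on_htn_treatment_with_dx),
    smoker = d$smoking == "current",
    diabetes = as.logical(d$on_glucose_treatment) | d$hba1c_pct >= 6.5)
}

#' Validate the tables of a cohort bundle
#'
#' Schema and plausibility checks: required columns, duplicated subject
#' ids, id alignment across tables, negative consumption or physiologic
#' values. Returns a report rather than failing.
#'
#' @param bundle A `cohort_bundle` (or a list with the same elements).
#' @return Data frame with columns `table`, `check`, `detail`; zero rows
#'   when everything passes.
#' @export
validate_cohort <- function(bundle) {
  fails <- list()
  add <- function(tbl, check, detail) {
    fails[[length(fails) + 1]] <<- data.frame(table = tbl, check = check,
                                              detail = detail)
  }
  ids <- bundle$demographics$subject_id
  if (anyDuplicated(ids)) {
    add("demographics", "duplicate_subject_id",
        paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (tbl in c("diet", "clinical")) {
    t_ids <- bundle[[tbl]]$subject_id
    if (anyDuplicated(t_ids)) {
      add(tbl, "duplicate_subject_id",
          paste(unique(t_ids[duplicated(t_ids)]), collapse = ", "))
    }
    if (!setequal(t_ids, ids)) add(tbl, "subject_id_mismatch",
                                   "ids differ from demographics")
  }
  need_diet <- setdiff(hei_diet_columns(), names(bundle$diet))
  if (length(need_diet)) {
    add("diet", "missing_columns", paste(need_diet, collapse = ", "))
  } else {
    for (col in setdiff(hei_diet_columns(), "sex")) {
      v <- bundle$diet[[col]]
      if (any(!is.na(v) & v < 0)) add("diet", "negative_value", col)
    }
  }
  for (col in c("waist_cm", "bmi", "sbp_mmhg", "dbp_mmhg",
                "triglycerides_mg_dl", "hdl_mg_dl", "glucose_mg_dl")) {
    if (!col %in% names(bundle$clinical)) {
      add("clinical", "missing_columns", col)
    } else {
      v <- bundle$clinical[[col]]
      if (any(!is.na(v) & v <= 0)) add("clinical", "nonpositive_value", col)
    }
  }
  if (!is.null(bundle$lipids)) {
    if (!setequal(rownames(bundle$lipids$values), ids)) {
      add("lipids", "subject_id_mismatch", "ids differ from demographics")
    }
    obs <- bundle$lipids$values[!bundle$lipids$below_lod]
    if (any(!is.na(obs) & obs < 0)) add("lipids", "negative_concentration", "")
  }
  if (length(fails)) do.call(rbind, fails) else
    data.frame(table = character(), check = character(), detail = character())
}

#' Run the full diet-lipidome-risk analysis pipeline
#'
#' Orchestrates, in order: HEI scoring (with exclusions), lipid QC (LOD
#' filter, below-LOD handling, Blom standardization pooled across waves),
#' signature fitting on the training wave (penalty by 10-fold CV),
#' leave-one-out cross-validated training scores and directly scored
#' testing wave, signature-HEI correlations, MetS classification, CVD risk
#' (eligibility filter, pooled cohort equations, normalization), and the
#' tiered association models. A manifest records seeds, subject counts at
#' every stage and exclusion reasons.
#'
#' @param bundle A `cohort_bundle` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param lod_threshold Below-LOD prevalence cutoff (default 0.20).
#' @param below_lod_policy See [handle_below_lod()].
#' @param lambda_rule,seed Passed to [hei_signature()].
#' @param normalize_method See [normalize_risk()].
#' @param stages Which stages to run after the signature:
#'   `"associations"` may be dropped for signature-only runs.
#' @return Object of class `hei_pipeline`: list with `hei`, `signature`
#'   (model), `scores` (per-subject table), `correlations`, `mets`, `risk`,
#'   `associations`, `analysis` (merged analysis table) and `manifest`.
#' @export
run_pipeline <- function(bundle, lod_threshold = 0.20,
                         below_lod_policy = "rank_low",
                         lambda_rule = "cv_min", seed = 1,
                         normalize_method = "rank_inverse_normal",
                         stages = c("mets", "risk", "associations")) {
  stopifnot(inherits(bundle, "cohort_bundle") || is.list(bundle))
  manifest <- list(seed = seed, lambda_rule = lambda_rule,
                   lod_threshold = lod_threshold,
                   below_lod_policy = below_lod_policy,
                   n_subjects = nrow(bundle$demographics))

  ## healthy eating index
  hei <- score_hei(bundle$diet)
  manifest$n_hei_scored <- sum(!hei$excluded)
  manifest$hei_exclusions <- attr(hei, "exclusions")

  ## lipid QC
  lip <- filter_by_lod(bundle$lipids, lod_threshold)
  manifest$n_species_input <- ncol(bundle$lipids$values)
  manifest$n_species_retained <- ncol(lip$values)
  z <- standardize_lipids(lip, policy = below_lod_policy, scope = "pooled")

  ## alignment: complete HEI + complete lipid rows
  wave <- bundle$demographics$wave[match(rownames(z),
                                         bundle$demographics$subject_id)]
  y_all <- hei$total[match(rownames(z), hei$subject_id)]
  complete <- !is.na(y_all) & stats::complete.cases(z)
  train <- complete & wave == "core"
  test <- complete & wave == "refresher"
  manifest$n_train <- sum(train); manifest$n_test <- sum(test)

  ## signature
  meta <- attr(z, "species_meta")
  model <- hei_signature(z[train, , drop = FALSE], y_all[train],
                         lambda_rule = lambda_rule, seed = seed,
                         species_meta = meta)
  loo <- loocv_signature_scores(z[train, , drop = FALSE], y_all[train],
                                model = model)
  test_scores <- if (any(test)) {
    predict(model, z[test, , drop = FALSE])
  } else numeric(0)

  scores <- data.frame(
    subject_id = c(rownames(z)[train], rownames(z)[test]),
    score = c(as.numeric(loo), as.numeric(test_scores)),
    provenance = c(rep("loocv_train", sum(train)),
                   rep("direct_test", sum(test))))
  cor_or_zero <- function(s, y) {
    if (length(s) < 3) return(list(r = NA_real_, p_value = NA_real_,
                                   n = length(s)))
    # an empty model defines the zero signature: its scores are refit
    # noise around zero and their correlation with the HEI is vacuous
    if (length(model$selected) == 0 || stats::sd(s) == 0) {
      return(list(r = 0, p_value = 1, n = length(s), degenerate = TRUE))
    }
    signature_cor(s, y)
  }
  correlations <- list(
    train = cor_or_zero(as.numeric(loo), y_all[train]),
    test = cor_or_zero(as.numeric(test_scores), y_all[test]),
    combined = cor_or_zero(scores$score, c(y_all[train], y_all[test])))
  manifest$lambda <- model$lambda
  manifest$n_selected <- length(model$selected)

  out <- list(hei = hei, signature = model, scores = scores,
              correlations = correlations, manifest = manifest)

  ## analysis table shared by the downstream stages
  an <- merge(bundle$demographics, bundle$clinical,
              by = intersect(names(bundle$demographics),
                             names(bundle$clinical)))
  an <- merge(an, scores, by = "subject_id")
  an <- merge(an, data.frame(subject_id = hei$subject_id, hei = hei$total),
              by = "subject_id")
  names(an)[names(an) == "score"] <- "signature"

  if ("mets" %in% stages) {
    mets <- classify_mets(bundle$clinical)
    out$mets <- cbind(data.frame(subject_id = bundle$clinical$subject_id),
                      mets)
    manifest$mets_prevalence <- mean(mets$mets, na.rm = TRUE)
    an <- merge(an, out$mets, by = "subject_id", all.x = TRUE)
  }

  if ("risk" %in% stages) {
    risk_in <- prepare_risk_inputs(bundle$demographics, bundle$clinical)
    elig <- cvd_eligibility(risk_in)
    risk10 <- pce_risk(elig$included)
    norm <- normalize_risk(risk10, normalize_method)
    out$risk <- data.frame(subject_id = elig$included$subject_id,
                           risk10y = risk10, cvr_norm = as.numeric(norm))
    attr(out$risk, "exclusions") <- elig$exclusions
    attr(out$risk, "normalize_method") <- normalize_method
    manifest$n_risk_eligible <- nrow(elig$included)
    an <- merge(an, out$risk, by = "subject_id", all.x = TRUE)
  }

  if ("associations" %in% stages) {
    biomarkers <- c(bmi = "bmi", ldl = "ldl_mg_dl", hdl = "hdl_mg_dl",
                    homa_ir = "homa_ir", insulin = "insulin_uiu_ml",
                    glucose = "glucose_mg_dl", hba1c = "hba1c_pct",
                    il6 = "il6_pg_ml", crp = "crp_mg_l")
    lin <- do.call(rbind, lapply(names(biomarkers), function(b) {
      col <- biomarkers[[b]]
      tiers <- if (b == "bmi") "I" else c("I", "II", "III")
      fit_tiered_linear(an, outcome = col, tiers = tiers)
    }))
    logi <- if ("mets" %in% stages) {
      do.call(rbind, lapply(
        c("mets", "central_adiposity", "high_tg", "low_hdl", "high_bp",
          "high_glucose"),
        function(o) fit_logistic_hei(an, o)))
    } else NULL
    cvr <- if ("risk" %in% stages && sum(!is.na(an$cvr_norm)) > 100) {
      fit_cvr_association(an)
    } else NULL
    out$associations <- list(signature_biomarkers = lin,
                             hei_mets = logi, signature_cvr = cvr)
  }

  out$analysis <- an
  out$manifest <- manifest
  class(out) <- "hei_pipeline"
  out
}

#' @export
print.hei_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("diet-lipidome-risk pipeline run\n")
  cat(sprintf("  subjects: %d (train %d / test %d); species %d -> %d after LOD filter\n",
              m$n_subjects, m$n_train, m$n_test, m$n_species_input,
              m$n_species_retained))
  cat(sprintf("  signature: %d species at lambda %.4g (%s)\n",
              m$n_selected, m$lambda, m$lambda_rule))
  cr <- x$correlations
  cat(sprintf("  signature-HEI r: train (LOO) %.3f, test %.3f, combined %.3f\n",
              cr$train$r, if (is.na(cr$test$r)) NA else cr$test$r,
              cr$combined$r))
  if (!is.null(m$mets_prevalence)) {
    cat(sprintf("  MetS prevalence: %.1f%%\n", 100 * m$mets_prevalence))
  }
  if (!is.null(m$n_risk_eligible)) {
    cat(sprintf("  CVD risk: %d eligible subjects\n", m$n_risk_eligible))
  }
  invisible(x)
}
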