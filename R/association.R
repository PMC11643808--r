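#' Covariate set for one adjustment tier
#'
#' The tiers nest by construction: Model I adjusts for sample origin and
#' sociodemographics (wave, age, sex, race); Model II adds BMI; Model III
#' adds the healthy eating index total.
#'
#' @param tier `"I"`, `"II"` or `"III"`.
#' @return Character vector of covariate column names.
#' @export
tier_covariates <- function(tier = c("I", "II", "III")) {
  tier <- match.arg(tier)
  base <- c("wave", "age", "sex", "race")
  switch(tier, I = base, II = c(base, "bmi"), III = c(base, "bmi", "hei"))
}

.zscore <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) stop("zero variance in a variable to standardize")
  (v - mean(v)) / s
}

.check_collinear <- function(fit) {
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear covariates dropped from the fit: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
}

.as_factors <- function(data) {
  # reference categories: refresher wave, female, non-white, postgraduate
  # education, current smoking
  if ("wave" %in% names(data) && !is.factor(data$wave)) {
    data$wave <- stats::relevel(factor(data$wave), ref = intersect(
      c("refresher", levels(factor(data$wave))[1]), unique(data$wave))[1])
  }
  if ("sex" %in% names(data) && !is.factor(data$sex)) {
    data$sex <- factor(data$sex, levels = intersect(c("female", "male"),
                                                    unique(data$sex)))
  }
  if ("race" %in% names(data) && !is.factor(data$race)) {
    data$race <- factor(data$race, levels = intersect(c("non_white", "white"),
                                                      unique(data$race)))
  }
  if ("education" %in% names(data) && !is.factor(data$education)) {
    data$education <- factor(data$education,
                             levels = intersect(c("postgraduate", "college",
                                                  "hs_or_less"),
                                                unique(data$education)))
  }
  if ("smoking" %in% names(data) && !is.factor(data$smoking)) {
    data$smoking <- factor(data$smoking,
                           levels = intersect(c("current", "former", "never"),
                                              unique(data$smoking)))
  }
  data
}

#' Linear association on standardized scales
#'
#' Ordinary least squares of a continuous outcome on an exposure plus
#' covariates, complete cases only. Exposure and outcome are z-scored on
#' the analysis sample (default) so coefficients are standardized and
#' comparable across biomarkers.
#'
#' @param data Data frame.
#' @param outcome,exposure Column names (numeric).
#' @param covariates Character vector of adjustment column names.
#' @param standardize Z-score outcome and exposure first (default TRUE).
#' @return One-row data frame: `outcome`, `exposure`, `estimate`, `lo`,
#'   `hi`, `p_value`, `n`, `scale`.
#' @export
assoc_linear <- function(data, outcome, exposure, covariates = character(),
                         standardize = TRUE) {
  cols <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (nrow(d) < 10 * (length(covariates) + 1)) {
    stop("too few complete cases (", nrow(d), ") for ",
         length(covariates) + 1, " model terms")
  }
  d <- .as_factors(d)
  if (standardize) {
    d[[outcome]] <- .zscore(d[[outcome]])
    d[[exposure]] <- .zscore(d[[exposure]])
  }
  rhs <- paste(c(sprintf("`%s`", exposure),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fit <- stats::lm(stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs)),
                   data = d)
  .check_collinear(fit)
  cn <- names(stats::coef(fit))
  key <- if (exposure %in% cn) exposure else sprintf("`%s`", exposure)
  est <- stats::coef(fit)[[key]]
  ci <- stats::confint(fit)[key, ]
  p <- summary(fit)$coefficients[key, 4]
  data.frame(outcome = outcome, exposure = exposure, estimate = est,
             lo = unname(ci[1]), hi = unname(ci[2]), p_value = p,
             n = nrow(d),
             scale = if (standardize) "std_beta" else "raw_beta")
}

#' Tiered linear models of a biomarker on the lipid signature
#'
#' Fits the three nested adjustment models (see [tier_covariates()]) for
#' one continuous outcome with the signature score as exposure and returns
#' a tidy table, one row per tier.
#'
#' @param data Analysis table with the outcome, `signature`, and the tier
#'   covariates (`wave`, `age`, `sex`, `race`, `bmi`, `hei`).
#' @param outcome Outcome column name.
#' @param exposure Exposure column (default `"signature"`).
#' @param tiers Subset of `c("I", "II", "III")`.
#' @return Data frame with one row per tier (`tier` column added).
#' @export
fit_tiered_linear <- function(data, outcome, exposure = "signature",
                              tiers = c("I", "II", "III")) {
  do.call(rbind, lapply(tiers, function(tt) {
    covs <- setdiff(tier_covariates(tt), outcome)
    row <- assoc_linear(data, outcome, exposure, covs)
    cbind(data.frame(tier = tt), row)
  }))
}

#' Logistic models of MetS (or a component) on the healthy eating index
#'
#' Maximum-likelihood logistic regression of a binary outcome on the HEI
#' total, adjusted for time of sampling, sex, race, age, educational level,
#' smoking status, and physical activity. The effect is reported as the
#' odds ratio per one HEI point with a Wald 95% CI.
#'
#' @param data Analysis table with the outcome, `hei`, and covariates
#'   `wave`, `sex`, `race`, `age`, `education`, `smoking`,
#'   `physical_activity`.
#' @param outcome Binary outcome column (e.g. `mets` or a criterion flag).
#' @param covariates Adjustment set (default the list above).
#' @return One-row data frame: `outcome`, `or`, `lo`, `hi`, `log_or`,
#'   `p_value`, `n`, `scale = "odds_ratio"`.
#' @export
fit_logistic_hei <- function(data, outcome,
                             covariates = c("wave", "sex", "race", "age",
                                            "education", "smoking",
                                            "physical_activity")) {
  cols <- c(outcome, "hei", covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  yv <- as.logical(d[[outcome]])
  if (length(unique(yv)) < 2) stop("outcome `", outcome, "` needs both classes")
  d <- .as_factors(d)
  d[[outcome]] <- yv
  rhs <- paste(c("hei", sprintf("`%s`", covariates)), collapse = " + ")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs)),
               data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || max(abs(stats::coef(fit)), na.rm = TRUE) > 15) {
    stop("separation detected in logistic fit for `", outcome,
         "`; consider a penalized model")
  }
  .check_collinear(fit)
  sm <- summary(fit)$coefficients["hei", ]
  est <- sm[1]; se <- sm[2]
  data.frame(outcome = outcome, or = exp(est),
             lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se),
             log_or = unname(est), p_value = unname(sm[4]), n = nrow(d),
             scale = "odds_ratio")
}

#' Tiered models of normalized cardiovascular risk on the signature
#'
#' The same nested adjustment ladder as [fit_tiered_linear()], with the
#' normalized 10-year risk as the dependent variable, restricted to the
#' eligibility-filtered subsample (rows with a non-missing `cvr_norm`).
#' Because the primary linear coefficient is standardized, an odds-ratio
#' style view `exp(estimate)` is also emitted, clearly labelled as derived
#' from the linear fit.
#'
#' @param data Analysis table containing `cvr_norm`, `signature` and the
#'   tier covariates.
#' @param tiers Subset of `c("I", "II", "III")`.
#' @return Data frame, one row per tier, with an extra `or_scale` column
#'   (`exp(estimate)`, derived) and its CI.
#' @export
fit_cvr_association <- function(data, tiers = c("I", "II", "III")) {
  d <- data[!is.na(data$cvr_norm), , drop = FALSE]
  out <- fit_tiered_linear(d, outcome = "cvr_norm", tiers = tiers)
  out$or_scale <- exp(out$estimate)
  out$or_lo <- exp(out$lo)
  out$or_hi <- exp(out$hi)
  out$or_note <- "derived: exp of standardized linear coefficient"
  out
}
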