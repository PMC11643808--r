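#' Pooled cohort equation coefficient tables
#'
#' The published 2013 ACC/AHA pooled cohort equations for 10-year
#' atherosclerotic cardiovascular disease risk: race- and sex-specific
#' log-coefficient tables, the group mean linear-predictor terms, and the
#' baseline 10-year survival probabilities. Risk is
#' `1 - s0 ^ exp(lp - mean_term)` where `lp` sums coefficient x covariate
#' over the group's terms (natural logs of age, total cholesterol, HDL-c
#' and systolic blood pressure, the published interactions, and the smoker
#' and diabetes indicators).
#'
#' Shipped as an inspectable data frame so the constants can be audited and
#' tested directly.
#'
#' @return Data frame with columns `group` (`white_male`, `white_female`,
#'   `black_male`, `black_female`), `term`, `coefficient`, plus per-group
#'   rows `baseline_survival` and `mean_term`.
#' @export
pce_coefficients <- function() {
  rows <- function(group, ...) {
    kv <- c(...)
    data.frame(group = group, term = names(kv), coefficient = unname(kv))
  }
  rbind(
    rows("white_male",
         ln_age = 12.344, ln_tc = 11.853, ln_age_ln_tc = -2.664,
         ln_hdl = -7.990, ln_age_ln_hdl = 1.769,
         ln_sbp_treated = 1.797, ln_sbp_untreated = 1.764,
         smoker = 7.837, ln_age_smoker = -1.795, diabetes = 0.658,
         mean_term = 61.18, baseline_survival = 0.9144),
    rows("white_female",
         ln_age = -29.799, ln_age_sq = 4.884,
         ln_tc = 13.540, ln_age_ln_tc = -3.114,
         ln_hdl = -13.578, ln_age_ln_hdl = 3.149,
         ln_sbp_treated = 2.019, ln_sbp_untreated = 1.957,
         smoker = 7.574, ln_age_smoker = -1.665, diabetes = 0.661,
         mean_term = -29.18, baseline_survival = 0.9665),
    rows("black_male",
         ln_age = 2.469, ln_tc = 0.302, ln_hdl = -0.307,
         ln_sbp_treated = 1.916, ln_sbp_untreated = 1.809,
         smoker = 0.549, diabetes = 0.645,
         mean_term = 19.54, baseline_survival = 0.8954),
    rows("black_female",
         ln_age = 17.114, ln_tc = 0.940,
         ln_hdl = -18.920, ln_age_ln_hdl = 4.475,
         ln_sbp_treated = 29.291, ln_age_ln_sbp_treated = -6.432,
         ln_sbp_untreated = 27.820, ln_age_ln_sbp_untreated = -6.087,
         smoker = 0.691, diabetes = 0.874,
         mean_term = 86.61, baseline_survival = 0.9533)
  )
}

#' Eligibility filter for the pooled cohort equations
#'
#' Keeps subjects inside the calculator's validity windows: age 40-79
#' years, total cholesterol 130-320 mg/dL, HDL-c 20-100 mg/dL, systolic
#' blood pressure 90-200 mmHg. "Between" is treated as inclusive at both
#' endpoints (clinical-calculator convention); subjects sitting exactly on
#' a window endpoint are flagged in the log so the convention is auditable.
#'
#' @param data Data frame with columns `age`, `total_chol_mg_dl`,
#'   `hdl_mg_dl`, `sbp_mmhg`.
#' @return List with `included` (eligible rows of `data`), `exclusions`
#'   (subject id + reason per excluded subject) and `boundary` (ids of
#'   included subjects on a window endpoint).
#' @export
cvd_eligibility <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("age", "total_chol_mg_dl", "hdl_mg_dl", "sbp_mmhg")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  id <- if ("subject_id" %in% names(data)) data$subject_id else seq_len(nrow(data))
  win <- list(age = c(40, 79), total_chol_mg_dl = c(130, 320),
              hdl_mg_dl = c(20, 100), sbp_mmhg = c(90, 200))
  inside <- rep(TRUE, nrow(data))
  reasons <- rep("", nrow(data))
  on_edge <- rep(FALSE, nrow(data))
  for (v in names(win)) {
    x <- data[[v]]
    bad <- is.na(x) | x < win[[v]][1] | x > win[[v]][2]
    reasons[bad] <- paste0(reasons[bad], ifelse(nchar(reasons[bad]), "; ", ""),
                           v, " outside [", win[[v]][1], ", ", win[[v]][2], "]")
    inside <- inside & !bad
    on_edge <- on_edge | (!is.na(x) & (x == win[[v]][1] | x == win[[v]][2]))
  }
  if (!any(inside)) warning("no subjects satisfy the eligibility windows")
  list(included = data[inside, , drop = FALSE],
       exclusions = data.frame(subject_id = id[!inside],
                               reason = reasons[!inside]),
       boundary = id[inside & on_edge])
}

#' 10-year ASCVD risk by the 2013 pooled cohort equations
#'
#' Deterministic 10-year atherosclerotic cardiovascular disease risk from
#' the published race- and sex-specific equations (see
#' [pce_coefficients()]). Subjects should already satisfy
#' [cvd_eligibility()]. Race groups other than African American are mapped
#' to the white/other coefficient set, as the published equations
#' recommend.
#'
#' @param data Data frame with columns `age`, `sex` (`"male"`/`"female"`),
#'   `race_group` (`"african_american"` or anything else, mapped to
#'   white/other), `total_chol_mg_dl`, `hdl_mg_dl`, `sbp_mmhg`,
#'   `treated_htn`, `smoker`, `diabetes` (logicals).
#' @return Numeric vector of risks, strictly inside (0, 1).
#' @export
pce_risk <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("age", "sex", "race_group", "total_chol_mg_dl", "hdl_mg_dl",
            "sbp_mmhg", "treated_htn", "smoker", "diabetes")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(data$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  grp <- paste0(ifelse(data$race_group == "african_american", "black", "white"),
                "_", data$sex)
  tab <- pce_coefficients()
  co <- function(g, term) {
    v <- tab$coefficient[tab$group == g & tab$term == term]
    if (length(v)) v else 0
  }
  la <- log(data$age); ltc <- log(data$total_chol_mg_dl)
  lh <- log(data$hdl_mg_dl); ls <- log(data$sbp_mmhg)
  trt <- as.logical(data$treated_htn)
  smk <- as.logical(data$smoker); dia <- as.logical(data$diabetes)

  risk <- numeric(nrow(data))
  for (g in unique(grp)) {
    i <- grp == g
    lp <- co(g, "ln_age") * la[i] + co(g, "ln_age_sq") * la[i]^2 +
      co(g, "ln_tc") * ltc[i] + co(g, "ln_age_ln_tc") * la[i] * ltc[i] +
      co(g, "ln_hdl") * lh[i] + co(g, "ln_age_ln_hdl") * la[i] * lh[i] +
      ifelse(trt[i],
             co(g, "ln_sbp_treated") * ls[i] +
               co(g, "ln_age_ln_sbp_treated") * la[i] * ls[i],
             co(g, "ln_sbp_untreated") * ls[i] +
               co(g, "ln_age_ln_sbp_untreated") * la[i] * ls[i]) +
      smk[i] * (co(g, "smoker") + co(g, "ln_age_smoker") * la[i]) +
      dia[i] * co(g, "diabetes")
    risk[i] <- 1 - co(g, "baseline_survival") ^ exp(lp - co(g, "mean_term"))
  }
  risk
}

#' Normalize estimated cardiovascular risk
#'
#' Maps risk probabilities to a normal z scale. The default
#' `"rank_inverse_normal"` applies the Blom rank-based normal scores to the
#' risk vector (distribution-free); `"direct_quantile"` applies the
#' standard-normal quantile function elementwise, `qnorm(risk)`.
#'
#' @param risk Numeric vector of risks in (0, 1).
#' @param method `"rank_inverse_normal"` or `"direct_quantile"`.
#' @return Numeric vector on the z scale, with `attr(, "method")`.
#' @export
normalize_risk <- function(risk,
                           method = c("rank_inverse_normal", "direct_quantile")) {
  method <- match.arg(method)
  ok <- !is.na(risk)
  if (any(risk[ok] <= 0 | risk[ok] >= 1)) stop("risks must lie strictly in (0, 1)")
  out <- switch(method,
                rank_inverse_normal = blom_transform(risk),
                direct_quantile = stats::qnorm(risk))
  attr(out, "method") <- method
  out
}
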