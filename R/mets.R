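#' Evaluate the five updated ATP III metabolic syndrome criteria
#'
#' Per-subject criterion flags, with the inequalities of the updated Adult
#' Treatment Panel III definition applied verbatim:
#' \itemize{
#'   \item central adiposity: waist > 102 cm (men) / > 88 cm (women), strict;
#'   \item high triglycerides: TG >= 150 mg/dL, or lipid-lowering treatment
#'     for hypertriglyceridemia;
#'   \item low HDL-c: < 40 mg/dL (men) / < 50 mg/dL (women), strict, or
#'     treatment for low HDL;
#'   \item high blood pressure: SBP >= 130 or DBP >= 85 mmHg, or
#'     antihypertensive medication with a prior hypertension diagnosis;
#'   \item high fasting glucose: >= 100 mg/dL, or treatment for
#'     hyperglycemia.
#' }
#' Missing medication flags default to `FALSE` with a warning (conservative
#' toward non-disease).
#'
#' @param clinical Data frame with columns `sex`, `waist_cm`,
#'   `triglycerides_mg_dl`, `hdl_mg_dl`, `sbp_mmhg`, `dbp_mmhg`,
#'   `glucose_mg_dl` and (optionally) logical `on_tg_treatment`,
#'   `on_hdl_treatment`, `on_htn_treatment_with_dx`, `on_glucose_treatment`.
#' @return Data frame of five logical columns `central_adiposity`,
#'   `high_tg`, `low_hdl`, `high_bp`, `high_glucose` (NA where
#'   unscorable).
#' @export
mets_criteria <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  need <- c("sex", "waist_cm", "triglycerides_mg_dl", "hdl_mg_dl",
            "sbp_mmhg", "dbp_mmhg", "glucose_mg_dl")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  flag <- function(col) {
    if (col %in% names(clinical)) {
      v <- clinical[[col]]
      v[is.na(v)] <- FALSE
      as.logical(v)
    } else {
      warning("medication flag `", col, "` absent: assuming untreated")
      rep(FALSE, nrow(clinical))
    }
  }
  tg_rx  <- flag("on_tg_treatment")
  hdl_rx <- flag("on_hdl_treatment")
  htn_rx <- flag("on_htn_treatment_with_dx")
  glu_rx <- flag("on_glucose_treatment")

  male <- clinical$sex == "male"
  waist_cut <- ifelse(male, 102, 88)
  hdl_cut <- ifelse(male, 40, 50)

  data.frame(
    central_adiposity = clinical$waist_cm > waist_cut,
    high_tg = clinical$triglycerides_mg_dl >= 150 | tg_rx,
    low_hdl = clinical$hdl_mg_dl < hdl_cut | hdl_rx,
    high_bp = clinical$sbp_mmhg >= 130 | clinical$dbp_mmhg >= 85 | htn_rx,
    high_glucose = clinical$glucose_mg_dl >= 100 | glu_rx
  )
}

#' Classify metabolic syndrome
#'
#' MetS is present when at least three of the five updated ATP III criteria
#' are abnormal. Subjects with any unevaluable criterion are flagged
#' unscorable (`mets = NA`) and listed in the exclusion log.
#'
#' @inheritParams mets_criteria
#' @return Data frame with the five criterion flags, `n_criteria` (0-5) and
#'   `mets` (logical); exclusion log in `attr(, "exclusions")`.
#' @export
classify_mets <- function(clinical) {
  cr <- mets_criteria(clinical)
  n_criteria <- rowSums(cr)
  out <- cbind(cr, data.frame(n_criteria = n_criteria,
                              mets = n_criteria >= 3))
  id <- if ("subject_id" %in% names(clinical)) clinical$subject_id
        else seq_len(nrow(clinical))
  bad <- which(is.na(n_criteria))
  attr(out, "exclusions") <- data.frame(
    subject_id = id[bad],
    reason = vapply(bad, function(i) {
      paste0("unscorable criterion(s): ",
             paste(names(cr)[is.na(cr[i, ])], collapse = ", "))
    }, character(1)))
  out
}
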