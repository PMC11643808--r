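#' MIDUS healthy eating index component names
#'
#' The ten food-group components of the MIDUS-HEI, in scoring order. Five
#' relate directly to the score (healthy foods), three inversely (unhealthy
#' foods), and two non-linearly (fermented dairy and alcohol).
#'
#' @return Character vector of length 10.
#' @export
hei_components <- function() {
  c("veg_fruit", "whole_grains", "oily_fish", "lean_meat",
    "nonmeat_protein", "sugared_bev", "high_fat_meat", "fast_food",
    "fermented_dairy", "alcohol")
}

#' Questionnaire columns required to score the MIDUS-HEI
#'
#' @return Character vector of column names expected in a diet table.
#' @export
hei_diet_columns <- function() {
  c("sex", "veg_fruit_per_day", "whole_grains_per_day", "oily_fish_per_week",
    "lean_meat_per_week", "nonmeat_protein_per_week", "sugared_bev_per_day",
    "high_fat_meat_per_week", "fast_food_per_week", "fermented_dairy_per_day",
    "alcohol_days_per_week", "alcohol_drinks_per_day")
}

# Count-typed intakes are floored to whole servings before band lookup;
# real-typed components ("<1" style bands) are banded on the raw value.
.floor_count <- function(v) ifelse(is.na(v), NA_real_, floor(v))

.score_veg_fruit <- function(v) {
  v <- .floor_count(v)
  ifelse(is.na(v), NA_real_,
    ifelse(v >= 5, 2, ifelse(v >= 3, 1, ifelse(v >= 1, 0.5, 0))))
}

.score_whole_grains <- function(v) {
  v <- .floor_count(v)
  ifelse(is.na(v), NA_real_, ifelse(v >= 3, 1, ifelse(v >= 1, 0.5, 0)))
}

.score_oily_fish <- function(v) {
  ifelse(is.na(v), NA_real_, ifelse(v >= 1, 1, ifelse(v > 0, 0.5, 0)))
}

.score_lean_meat <- function(v) {
  v <- .floor_count(v)
  ifelse(is.na(v), NA_real_, ifelse(v >= 3, 1, ifelse(v >= 1, 0.5, 0)))
}

.score_nonmeat_protein <- function(v) {
  v <- .floor_count(v)
  ifelse(is.na(v), NA_real_, ifelse(v >= 3, 1, ifelse(v >= 1, 0.5, 0)))
}

.score_sugared_bev <- function(v) {
  v <- .floor_count(v)
  ifelse(is.na(v), NA_real_, ifelse(v >= 4, 0, ifelse(v >= 1, 0.5, 1)))
}

.score_high_fat_meat <- function(v) {
  v <- .floor_count(v)
  ifelse(is.na(v), NA_real_, ifelse(v >= 3, 0, ifelse(v >= 1, 0.5, 1)))
}

.score_fast_food <- function(v) {
  ifelse(is.na(v), NA_real_, ifelse(v >= 1, 0, ifelse(v > 0, 0.5, 1)))
}

.score_fermented_dairy <- function(v) {
  ifelse(is.na(v), NA_real_,
    ifelse(v >= 2 & v < 4, 1,
      ifelse((v >= 1 & v < 2) | (v >= 4 & v < 5), 0.5, 0)))
}

# Alcohol is scored from drinking frequency (days/week), quantity
# (drinks/day) and sex. Nondrinkers and over-limit drinkers (men > 2,
# women > 1 drinks/day) score 0; within-limit drinkers score 1 at >= 3
# drinking days/week and 0.5 below that.
.score_alcohol <- function(days, drinks, sex) {
  days <- .floor_count(days)
  limit <- ifelse(sex == "male", 2, ifelse(sex == "female", 1, NA_real_))
  out <- rep(NA_real_, length(days))
  known <- !is.na(days) & !is.na(drinks) & !is.na(limit)
  nondrinker <- known & (days == 0 | drinks == 0)
  over <- known & !nondrinker & drinks > limit
  within <- known & !nondrinker & !over
  out[nondrinker | over] <- 0
  out[within & days >= 3] <- 1
  out[within & days < 3] <- 0.5
  out
}

#' Score one MIDUS-HEI component
#'
#' Returns the banded score for a single food-group component. Every
#' component contributes 1 point when the recommended intake criterion is
#' fully met, 0.5 when partially met, and 0 otherwise; the combined
#' vegetables-and-fruits component alone can contribute 2 points (its ladder
#' is 0 / 0.5 / 1 / 2). Count-typed intakes (servings asked as whole
#' servings) are floored before band lookup; components with genuine
#' fractional bands (oily fish, fast food, fermented dairy) are banded on
#' the raw value.
#'
#' @param component One of [hei_components()].
#' @param value Intake for the component, in its questionnaire units
#'   (servings/day or servings/week; ignored for `"alcohol"`).
#' @param sex `"male"` or `"female"`; required for `"alcohol"`.
#' @param days Drinking frequency, days/week (alcohol only).
#' @param drinks Usual quantity, drinks/day on drinking days (alcohol only).
#' @return Numeric vector of component scores (`NA` where unscorable).
#' @examples
#' hei_component_score("veg_fruit", 5)   # 2
#' hei_component_score("oily_fish", 1)   # 1
#' hei_component_score("alcohol", sex = "female", days = 3, drinks = 1)  # 1
#' @export
hei_component_score <- function(component, value = NULL, sex = NULL,
                                days = NULL, drinks = NULL) {
  component <- match.arg(component, hei_components())
  if (component == "alcohol") {
    if (is.null(sex) || is.null(days) || is.null(drinks)) {
      stop("alcohol scoring needs `sex`, `days` and `drinks`")
    }
    return(.score_alcohol(days, drinks, sex))
  }
  if (is.null(value)) stop("`value` is required for component ", component)
  switch(component,
    veg_fruit       = .score_veg_fruit(value),
    whole_grains    = .score_whole_grains(value),
    oily_fish       = .score_oily_fish(value),
    lean_meat       = .score_lean_meat(value),
    nonmeat_protein = .score_nonmeat_protein(value),
    sugared_bev     = .score_sugared_bev(value),
    high_fat_meat   = .score_high_fat_meat(value),
    fast_food       = .score_fast_food(value),
    fermented_dairy = .score_fermented_dairy(value))
}

#' Score the MIDUS healthy eating index
#'
#' Computes the 10 component scores and the 0-11 total for each subject of
#' a diet questionnaire table. Subjects with any unscorable component
#' (missing intake, or missing sex for the alcohol component) are excluded
#' with a logged reason, mirroring the source cohort's exclusion rule, unless
#' `allow_partial = TRUE`, in which case the total sums the scorable
#' components only.
#'
#' @param diet Data frame with the columns of [hei_diet_columns()], plus an
#'   optional `subject_id` column.
#' @param allow_partial Keep subjects with missing components and sum what
#'   can be scored (default `FALSE`: exclude).
#' @return An object of class `hei_scores`: a data frame with one row per
#'   subject, the ten component scores, `total`, `n_missing`, and `excluded`
#'   (logical). The exclusion log is in `attr(, "exclusions")` (subject id +
#'   missing components).
#' @examples
#' d <- data.frame(sex = "female", veg_fruit_per_day = 5,
#'   whole_grains_per_day = 3, oily_fish_per_week = 1, lean_meat_per_week = 3,
#'   nonmeat_protein_per_week = 3, sugared_bev_per_day = 0,
#'   high_fat_meat_per_week = 0, fast_food_per_week = 0,
#'   fermented_dairy_per_day = 2, alcohol_days_per_week = 3,
#'   alcohol_drinks_per_day = 1)
#' score_hei(d)$total  # 11
#' @export
score_hei <- function(diet, allow_partial = FALSE) {
  stopifnot(is.data.frame(diet))
  missing_cols <- setdiff(hei_diet_columns(), names(diet))
  if (length(missing_cols)) {
    stop("diet table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  id <- if ("subject_id" %in% names(diet)) diet$subject_id else seq_len(nrow(diet))

  sc <- data.frame(
    veg_fruit       = .score_veg_fruit(diet$veg_fruit_per_day),
    whole_grains    = .score_whole_grains(diet$whole_grains_per_day),
    oily_fish       = .score_oily_fish(diet$oily_fish_per_week),
    lean_meat       = .score_lean_meat(diet$lean_meat_per_week),
    nonmeat_protein = .score_nonmeat_protein(diet$nonmeat_protein_per_week),
    sugared_bev     = .score_sugared_bev(diet$sugared_bev_per_day),
    high_fat_meat   = .score_high_fat_meat(diet$high_fat_meat_per_week),
    fast_food       = .score_fast_food(diet$fast_food_per_week),
    fermented_dairy = .score_fermented_dairy(diet$fermented_dairy_per_day),
    alcohol         = .score_alcohol(diet$alcohol_days_per_week,
                                     diet$alcohol_drinks_per_day, diet$sex))

  n_missing <- rowSums(is.na(sc))
  excluded <- !allow_partial & n_missing > 0
  total <- if (allow_partial) rowSums(sc, na.rm = TRUE) else rowSums(sc)
  total[excluded] <- NA_real_

  out <- cbind(data.frame(subject_id = id), sc,
               data.frame(total = total, n_missing = n_missing,
                          excluded = excluded))
  bad <- which(n_missing > 0)
  exclusions <- data.frame(
    subject_id = id[bad],
    reason = vapply(bad, function(i) {
      paste0("unscorable component(s): ",
             paste(names(sc)[is.na(sc[i, ])], collapse = ", "))
    }, character(1)))
  attr(out, "exclusions") <- exclusions
  class(out) <- c("hei_scores", class(out))
  out
}

#' @export
print.hei_scores <- function(x, ...) {
  if (!all(c("excluded", "total") %in% names(x))) {
    return(print.data.frame(x, ...))
  }
  cat("MIDUS-HEI scores: ", nrow(x), " subjects, ",
      sum(x$excluded), " excluded\n", sep = "")
  ok <- !x$excluded & !is.na(x$total)
  if (any(ok)) {
    cat(sprintf("  total: mean %.2f, sd %.2f, range [%g, %g]\n",
                mean(x$total[ok]), stats::sd(x$total[ok]),
                min(x$total[ok]), max(x$total[ok])))
  }
  invisible(x)
}
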