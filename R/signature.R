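#' Fit the diet-quality lipid signature by LASSO
#'
#' Regresses a healthy-eating-index total on Blom-standardized lipid
#' species with an L1 penalty, selecting species and weights
#' simultaneously. The penalty is chosen by 10-fold cross-validation on the
#' training data (`lambda_rule = "cv_min"`, the default, minimizes CV mean
#' squared error; `"cv_1se"` takes the one-standard-error rule) or supplied
#' directly (`"fixed"`). Fitting is delegated to \pkg{glmnet}; predictors
#' enter pre-standardized (no internal re-standardization), matching the
#' pipeline's order of operations in which the rank-based normal scores are
#' already on a common scale.
#'
#' The subject-level signature score is the intercept-free weighted sum of
#' the selected species (see [predict.hei_signature()]); the intercept is
#' kept in the object for full linear prediction.
#'
#' @param x Numeric matrix of standardized lipid values (subjects x
#'   species), e.g. from [standardize_lipids()].
#' @param y Numeric vector of HEI totals, aligned with rows of `x`.
#' @param lambda_rule `"cv_min"`, `"cv_1se"` or `"fixed"`.
#' @param lambda Penalty value when `lambda_rule = "fixed"`.
#' @param nfolds CV folds (default 10).
#' @param seed Integer seed controlling CV fold assignment; required for
#'   the CV rules so the selection is reproducible.
#' @param species_meta Optional species metadata (columns `species`,
#'   `class`) used by [summary.hei_signature()] and
#'   [signature_class_summary()].
#' @return Object of class `hei_signature`: list with `weights` (named
#'   vector over all species, zero where unselected), `selected`,
#'   `intercept`, `lambda`, `lambda_rule`, `n`, `p`, `seed`,
#'   `species_meta`.
#' @export
hei_signature <- function(x, y, lambda_rule = c("cv_min", "cv_1se", "fixed"),
                          lambda = NULL, nfolds = 10, seed = NULL,
                          species_meta = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  if (is.null(species_meta) && !is.null(attr(x, "species_meta"))) {
    species_meta <- attr(x, "species_meta")
  }
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("complete rows required: drop NA subjects first")
  if (nrow(x) <= 20) stop("need more than 20 subjects to fit the signature")
  if (stats::sd(y) == 0) stop("outcome has zero variance")

  if (lambda_rule == "fixed") {
    if (is.null(lambda)) stop("lambda_rule = 'fixed' needs `lambda`")
    fit <- glmnet::glmnet(x, y, family = "gaussian", standardize = FALSE)
    cf <- glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = x, y = y)
  } else {
    if (is.null(seed)) stop("CV lambda selection needs `seed` for fold assignment")
    set.seed(as.integer(seed))
    cvfit <- glmnet::cv.glmnet(x, y, family = "gaussian", nfolds = nfolds,
                               standardize = FALSE)
    lambda <- if (lambda_rule == "cv_min") cvfit$lambda.min else cvfit$lambda.1se
    cf <- glmnet::coef.glmnet(cvfit$glmnet.fit, s = lambda, exact = TRUE,
                              x = x, y = y)
  }
  cf <- as.numeric(cf)  # intercept first
  weights <- cf[-1]
  names(weights) <- colnames(x)

  structure(list(
    weights = weights,
    selected = colnames(x)[weights != 0],
    intercept = cf[1],
    lambda = lambda,
    lambda_rule = lambda_rule,
    n = nrow(x), p = ncol(x),
    seed = seed,
    species_meta = species_meta
  ), class = "hei_signature")
}

#' @export
print.hei_signature <- function(x, ...) {
  cat("Lipid signature of diet quality (lasso)\n")
  cat(sprintf("  n = %d subjects, %d candidate species, %d selected\n",
              x$n, x$p, length(x$selected)))
  cat(sprintf("  lambda = %.5g (%s)\n", x$lambda, x$lambda_rule))
  if (length(x$selected)) {
    w <- sort(abs(x$weights[x$selected]), decreasing = TRUE)
    top <- utils::head(names(w), 5)
    cat("  largest |weights|: ",
        paste(sprintf("%s (%.3f)", top, x$weights[top]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.hei_signature <- function(object, all = FALSE, ...) {
  if (all) c("(Intercept)" = object$intercept, object$weights)
  else object$weights[object$selected]
}

#' @export
summary.hei_signature <- function(object, ...) {
  out <- list(model = object,
              class_summary = tryCatch(signature_class_summary(object),
                                       error = function(e) NULL))
  class(out) <- "summary.hei_signature"
  out
}

#' @export
print.summary.hei_signature <- function(x, ...) {
  print(x$model)
  if (!is.null(x$class_summary) && nrow(x$class_summary)) {
    cat("  selected species by lipid class:\n")
    cs <- x$class_summary
    for (i in seq_len(nrow(cs))) {
      cat(sprintf("    %-8s %3d  (%.1f%%)\n", cs$class[i], cs$n[i], cs$percent[i]))
    }
  }
  invisible(x)
}

#' Plot the signature weights
#'
#' Horizontal bar chart of the selected species' LASSO weights, sorted by
#' magnitude.
#'
#' @param x A [hei_signature()] model.
#' @param max_species Show at most this many species (largest |weight|).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.hei_signature <- function(x, max_species = 30, ...) {
  w <- coef(x)
  if (!length(w)) {
    warning("empty model: nothing to plot")
    return(invisible(NULL))
  }
  w <- w[order(abs(w), decreasing = TRUE)]
  w <- utils::head(w, max_species)
  w <- rev(w)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(w, horiz = TRUE, las = 1, cex.names = 0.6,
                    xlab = "lasso weight", ...)
  invisible(x)
}

#' Apply a fitted signature to new lipid profiles
#'
#' `type = "signature"` (default) returns the intercept-free weighted sum of
#' the selected species, the subject-level lipid signature score;
#' `type = "response"` adds the intercept (the full linear prediction of the
#' HEI total).
#'
#' @param object A [hei_signature()] model.
#' @param newx Standardized lipid matrix containing every selected species
#'   as named columns.
#' @param type `"signature"` or `"response"`.
#' @param ... Unused.
#' @return Numeric vector of scores with `attr(, "provenance") =
#'   "direct_test"`.
#' @export
predict.hei_signature <- function(object, newx,
                                  type = c("signature", "response"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  missing_sp <- setdiff(object$selected, colnames(newx))
  if (length(missing_sp)) {
    stop("newx lacks selected species: ", paste(missing_sp, collapse = ", "))
  }
  if (length(object$selected)) {
    s <- drop(newx[, object$selected, drop = FALSE] %*%
                object$weights[object$selected])
  } else {
    s <- rep(0, nrow(newx))
  }
  if (type == "response") s <- s + object$intercept
  structure(s, provenance = "direct_test")
}

#' Leave-one-out cross-validated signature scores
#'
#' Out-of-sample signature scores for the training subjects: for each
#' subject i the lasso is refitted at the model's penalty on the remaining
#' n - 1 subjects and subject i is scored by that refit, so no subject's
#' lipids inform their own score. The penalty is selected once on the full
#' training set and held fixed across the refits. Refits run through an
#' internal warm-started coordinate-descent solver that minimizes the same
#' objective as \pkg{glmnet} (agreement is enforced by tests).
#'
#' @param x,y Training data as in [hei_signature()].
#' @param model A fitted [hei_signature()] on `x, y` (supplies `lambda` and
#'   the warm start). Alternatively pass `lambda` directly.
#' @param lambda Penalty; defaults to `model$lambda`.
#' @return Numeric scores, one per row of `x`, with
#'   `attr(, "provenance") = "loocv_train"`.
#' @export
loocv_signature_scores <- function(x, y, model = NULL, lambda = NULL) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (nrow(x) < 10) stop("n < 10: too few subjects for leave-one-out refits")
  if (is.null(lambda)) {
    if (is.null(model)) stop("supply `model` or `lambda`")
    lambda <- model$lambda
  }
  warm <- if (!is.null(model) && identical(model$p, ncol(x))) {
    unname(model$weights)
  } else {
    rep(0, ncol(x))
  }
  s <- .cd_lasso_loo_scores(x, as.numeric(y), lambda, warm)
  structure(as.numeric(s), provenance = "loocv_train")
}

#' Correlation between signature scores and the diet index
#'
#' Pearson correlation with a two-sided p-value from the t distribution
#' (via [stats::cor.test()]).
#'
#' @param scores Numeric signature scores.
#' @param y HEI totals, aligned.
#' @return List with `r`, `p_value`, `n`.
#' @export
signature_cor <- function(scores, y) {
  ok <- !is.na(scores) & !is.na(y)
  scores <- as.numeric(scores)[ok]; y <- y[ok]
  if (length(y) < 3) stop("need at least 3 aligned pairs")
  if (stats::sd(scores) == 0 || stats::sd(y) == 0) {
    stop("zero variance in scores or outcome")
  }
  ct <- stats::cor.test(scores, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(y))
}

#' Lipid-class composition of a fitted signature
#'
#' Percentage of the selected species falling in each lipid class
#' (triglycerides, phosphatidylcholines, ether-linked
#' phosphatidylethanolamines, ...). Percentages sum to 100.
#'
#' @param model A [hei_signature()].
#' @param species_meta Optional metadata (`species`, `class`); defaults to
#'   the metadata stored in the model.
#' @return Data frame with `class`, `n`, `percent`, sorted by descending
#'   percentage; empty for an empty model.
#' @export
signature_class_summary <- function(model, species_meta = NULL) {
  stopifnot(inherits(model, "hei_signature"))
  if (is.null(species_meta)) species_meta <- model$species_meta
  if (!length(model$selected)) {
    return(data.frame(class = character(), n = integer(), percent = numeric()))
  }
  if (is.null(species_meta)) stop("no species metadata available")
  idx <- match(model$selected, species_meta$species)
  if (anyNA(idx)) {
    stop("metadata lacks selected species: ",
         paste(model$selected[is.na(idx)], collapse = ", "))
  }
  tab <- table(species_meta$class[idx])
  out <- data.frame(class = names(tab), n = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(model$selected))
  out <- out[order(-out$percent, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
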