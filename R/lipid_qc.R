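#' Construct a lipid concentration matrix
#'
#' Container for a subjects x species concentration matrix together with a
#' below-limit-of-detection mask and species metadata (lipid class and
#' fatty-acid composition), as delivered by a quantitative LC-MS panel.
#'
#' @param values Numeric matrix, subjects in rows, species in columns;
#'   column names are species identifiers (unique), row names subject ids.
#' @param below_lod Logical matrix of the same shape flagging measurements
#'   below the lower limit of detection (default: none).
#' @param species_meta Data frame with columns `species`, `class` and
#'   optionally `fa_composition`, one row per species (default: class
#'   `"unknown"`).
#' @return An object of class `lipid_matrix`.
#' @export
lipid_matrix <- function(values, below_lod = NULL, species_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("lipid_", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("species identifiers must be unique")
  if (is.null(below_lod)) {
    below_lod <- matrix(FALSE, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  below_lod <- as.matrix(below_lod)
  if (!all(dim(below_lod) == dim(values))) {
    stop("below_lod mask shape does not match values")
  }
  dimnames(below_lod) <- dimnames(values)
  if (is.null(species_meta)) {
    species_meta <- data.frame(species = colnames(values),
                               class = "unknown",
                               fa_composition = NA_character_)
  }
  if (!all(c("species", "class") %in% names(species_meta))) {
    stop("species_meta needs `species` and `class` columns")
  }
  if (!all(colnames(values) %in% species_meta$species)) {
    stop("species_meta does not cover all species")
  }
  species_meta <- species_meta[match(colnames(values), species_meta$species), ,
                               drop = FALSE]
  rownames(species_meta) <- NULL
  structure(list(values = values, below_lod = mode_logical(below_lod),
                 species_meta = species_meta),
            class = "lipid_matrix")
}

mode_logical <- function(m) { storage.mode(m) <- "logical"; m }

#' @export
print.lipid_matrix <- function(x, ...) {
  cat("lipid_matrix: ", nrow(x$values), " subjects x ", ncol(x$values),
      " species; ", sprintf("%.1f%%", 100 * mean(x$below_lod)),
      " of cells below LOD\n", sep = "")
  invisible(x)
}

#' @export
dim.lipid_matrix <- function(x) dim(x$values)

#' Filter lipid species by below-LOD prevalence
#'
#' Retains exactly the species whose fraction of below-detection-limit
#' measurements is strictly less than `threshold` (default 20%, the panel
#' inclusion rule used for serum lipidomics QC); species at or above the
#' threshold are dropped. Subjects are unchanged. Idempotent.
#'
#' @param x A [lipid_matrix()].
#' @param threshold Maximum tolerated below-LOD fraction (exclusive).
#' @return A `lipid_matrix` with the retained species; dropped species and
#'   their below-LOD fractions are recorded in `attr(, "dropped")`.
#' @export
filter_by_lod <- function(x, threshold = 0.20) {
  stopifnot(inherits(x, "lipid_matrix"), threshold > 0)
  frac <- colMeans(x$below_lod)
  keep <- frac < threshold
  if (!any(keep)) {
    stop("no species retained at below-LOD threshold ", threshold,
         "; review the threshold or the panel")
  }
  out <- lipid_matrix(x$values[, keep, drop = FALSE],
                      x$below_lod[, keep, drop = FALSE],
                      x$species_meta[keep, , drop = FALSE])
  attr(out, "dropped") <- data.frame(species = colnames(x$values)[!keep],
                                     below_lod_fraction = unname(frac[!keep]))
  out
}

#' Impute or re-rank below-LOD measurements
#'
#' Prepares left-censored cells of retained species for rank-based
#' standardization. Policies: `"rank_low"` (default) forces all below-LOD
#' cells of a species beneath every observed value so they share the lowest
#' tied rank; `"half_min"` replaces them with half the minimum observed
#' concentration; `"zero"` replaces them with 0.
#'
#' @param x A [lipid_matrix()] (already LOD-filtered).
#' @param policy One of `"rank_low"`, `"half_min"`, `"zero"`.
#' @return A `lipid_matrix` with below-LOD cells replaced; the mask is kept.
#' @export
handle_below_lod <- function(x, policy = c("rank_low", "half_min", "zero")) {
  stopifnot(inherits(x, "lipid_matrix"))
  policy <- match.arg(policy)
  v <- x$values
  for (j in seq_len(ncol(v))) {
    flag <- x$below_lod[, j]
    if (!any(flag)) next
    obs <- v[!flag, j]
    v[flag, j] <- switch(policy,
      # strictly below every observed value -> shared minimal tied rank
      rank_low = if (length(obs)) min(obs) - 1 else 0,
      half_min = if (length(obs)) min(obs) / 2 else 0,
      zero = 0)
  }
  out <- lipid_matrix(v, x$below_lod, x$species_meta)
  attr(out, "below_lod_policy") <- policy
  out
}

#' Blom rank-based inverse-normal transformation
#'
#' Maps a variable to approximate standard-normal scores through its ranks:
#' `z_i = qnorm((r_i - 3/8) / (n + 1/4))` with `r_i` the (average-tie) rank
#' of observation `i` among the `n` non-missing values. The classical Blom
#' offset 3/8 is used. The output is a monotone function of the ranks, hence
#' invariant to any strictly monotone transform of the input.
#'
#' @param x Numeric vector; `NA`s are propagated.
#' @return Numeric vector of normal scores. An all-constant input yields
#'   all zeros with a warning (degenerate ranks).
#' @examples
#' blom_transform(c(3, 1, 2))  # approx -0.8694, 0.8694, 0
#' @export
blom_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  if (n == 0) return(out)
  xs <- x[ok]
  if (n == 1L) {
    out[ok] <- stats::qnorm((1 - 3 / 8) / (1 + 1 / 4))  # exactly 0
    return(out)
  }
  if (length(unique(xs)) == 1L) {
    warning("constant input: Blom scores are all zero")
    out[ok] <- 0
    return(out)
  }
  r <- rank(xs, ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Standardize a lipid matrix to Blom normal scores
#'
#' Applies [handle_below_lod()] then [blom_transform()] column by column.
#' By default all subjects are pooled before ranking (the transformation is
#' applied once, before any train/test split); `scope = "by_wave"` ranks
#' within the groups of `wave`.
#'
#' @param x A [lipid_matrix()], typically LOD-filtered.
#' @param policy Below-LOD handling policy, see [handle_below_lod()].
#' @param scope `"pooled"` (default) or `"by_wave"`.
#' @param wave Factor/character of length `nrow(x$values)`; required for
#'   `scope = "by_wave"`.
#' @return A numeric matrix of normal scores (subjects x retained species)
#'   with `attr(, "retained_species")` and `attr(, "species_meta")`.
#' @export
standardize_lipids <- function(x, policy = "rank_low",
                               scope = c("pooled", "by_wave"), wave = NULL) {
  stopifnot(inherits(x, "lipid_matrix"))
  scope <- match.arg(scope)
  x <- handle_below_lod(x, policy)
  v <- x$values
  z <- v
  if (scope == "pooled") {
    for (j in seq_len(ncol(v))) z[, j] <- blom_transform(v[, j])
  } else {
    if (is.null(wave) || length(wave) != nrow(v)) {
      stop("`wave` of length nrow(x) is required for by-wave standardization")
    }
    for (g in unique(wave)) {
      rows <- wave == g
      for (j in seq_len(ncol(v))) z[rows, j] <- blom_transform(v[rows, j])
    }
  }
  attr(z, "retained_species") <- colnames(v)
  attr(z, "species_meta") <- x$species_meta
  z
}
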