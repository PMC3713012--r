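#' Convert specific lysis to a recognition category
#'
#' Thresholds use strict inequality: lysis above 60% gives +4, above 40%
#' +3, above 20% +2, above 10% +1, and anything at or below 10% counts
#' as lack of significant specific lysis (-1).
#'
#' @param percent specific lysis percentage(s) in \[0, 100\].
#' @return integer category vector with values in \{-1, 1, 2, 3, 4\}.
#' @export
lysis_to_category <- function(percent) {
  if (any(percent < 0 | percent > 100)) {
    stop("specific lysis must be between 0 and 100 percent")
  }
  out <- ifelse(percent > 60, 4L,
         ifelse(percent > 40, 3L,
         ifelse(percent > 20, 2L,
         ifelse(percent > 10, 1L, -1L))))
  as.integer(out)
}

#' Per-clone recognition profile of one peptide
#'
#' Supply either raw specific-lysis percentages (converted by
#' [lysis_to_category()]) or categories directly.
#'
#' @param peptide_id peptide label.
#' @param lysis per-clone specific lysis percentages.
#' @param categories per-clone categories in \{-1, 1, 2, 3, 4\}.
#' @param n_clones expected clone count (default: length of the data;
#'   17 for the reference assay panel).
#' @return object of class `CloneRecognitionProfile`.
#' @export
clone_profile <- function(peptide_id, lysis = NULL, categories = NULL,
                          n_clones = NULL) {
  if (is.null(categories)) {
    if (is.null(lysis)) stop("supply lysis or categories")
    categories <- lysis_to_category(lysis)
  } else {
    categories <- as.integer(categories)
    if (anyNA(categories)) stop("missing clone entry in profile")
    if (!all(categories %in% c(-1L, 1L, 2L, 3L, 4L))) {
      stop("categories must be -1, +1, +2, +3 or +4")
    }
  }
  if (anyNA(categories)) stop("missing clone entry in profile")
  if (is.null(n_clones)) n_clones <- length(categories)
  if (length(categories) != n_clones) {
    stop(sprintf("expected %d clone entries, got %d", n_clones,
                 length(categories)))
  }
  structure(list(peptide_id = as.character(peptide_id),
                 categories = categories, lysis = lysis,
                 n_clones = n_clones),
            class = "CloneRecognitionProfile")
}

#' Cross-reactivity score of a peptide
#'
#' Sum of the per-clone categories; with 17 clones the score ranges from
#' -17 (no clone shows significant lysis) to 68 (all clones above 60%).
#'
#' @param profile a `CloneRecognitionProfile`.
#' @return integer score.
#' @export
cross_reactivity_score <- function(profile) {
  sum(profile$categories)
}

#' Clone-count score of a peptide
#'
#' Number of clones with a positive recognition category; an alternative
#' activity scale running from 0 to the clone count.
#'
#' @param profile a `CloneRecognitionProfile`.
#' @return integer count.
#' @export
clone_count_score <- function(profile) {
  sum(profile$categories >= 1L)
}

#' Titration curve of a peptide on one clone
#'
#' @param concentrations peptide concentrations in Molar, strictly
#'   positive; stored sorted descending (serial dilution order).
#' @param lysis specific lysis percentages, one per concentration.
#' @param clone clone id (optional).
#' @return object of class `TitrationCurve`.
#' @export
titration_curve <- function(concentrations, lysis, clone = NA_character_) {
  stopifnot(length(concentrations) == length(lysis))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  ord <- order(concentrations, decreasing = TRUE)
  structure(list(concentrations = concentrations[ord], lysis = lysis[ord],
                 clone = clone),
            class = "TitrationCurve")
}

#' EC50 from a titration curve
#'
#' Functional avidity read-out: the concentration at which the fitted
#' line over the linear domain of the curve reaches half of
#' `max_lysis`. The linear domain is the longest consecutive run of
#' points with lysis between 20% and 80% of `max_lysis` (the
#' conventional operational definition); lysis is regressed on
#' log10(concentration) over that run.
#'
#' @param curve a `TitrationCurve`.
#' @param max_lysis maximal lysis capacity of the clone (default: the
#'   curve maximum).
#' @return EC50 in Molar.
#' @export
ec50 <- function(curve, max_lysis = max(curve$lysis)) {
  target <- 0.5 * max_lysis
  if (max(curve$lysis) < target) {
    stop("50% of maximal lysis not reached by the titration curve")
  }
  inband <- curve$lysis >= 0.2 * max_lysis & curve$lysis <= 0.8 * max_lysis
  runs <- rle(inband)
  if (!any(runs$values)) stop("no linear domain (no points between 20% and 80% of max)")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  idx <- starts[best]:ends[best]
  if (length(idx) < 2L) stop("linear domain has fewer than 2 points; cannot fit")
  lx <- log10(curve$concentrations[idx])
  fit <- stats::lm(curve$lysis[idx] ~ lx)
  b <- stats::coef(fit)
  if (abs(b[2]) < 1e-12) stop("flat linear domain; EC50 undefined")
  unname(10^((target - b[1]) / b[2]))
}

#' Log10 relative functional avidity
#'
#' `log10(ec50_ref / ec50_x)`: -1 means the test peptide needs a 10-fold
#' higher concentration than the reference to reach half-maximal lysis.
#'
#' @param ec50_ref reference-peptide EC50 in Molar.
#' @param ec50_x test-peptide EC50 in Molar.
#' @return dimensionless log10 ratio.
#' @export
relative_avidity_log <- function(ec50_ref, ec50_x) {
  if (any(c(ec50_ref, ec50_x) <= 0)) stop("EC50 values must be positive")
  log10(ec50_ref / ec50_x)
}

#' Average relative avidity over clones
#'
#' @param values per-clone log10 relative avidities.
#' @return arithmetic mean.
#' @export
mean_over_clones <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  mean(values)
}

#' Normalized competition-assay lysis
#'
#' `100 * lysis_with_competitor / lysis_reference`; values can exceed
#' 100% when the competitor condition out-lyses the reference.
#'
#' @param lysis_with_competitor specific lysis with competitor present.
#' @param lysis_reference reference lysis (antigenic peptide alone).
#' @return normalized percent lysis.
#' @export
normalize_competition <- function(lysis_with_competitor, lysis_reference) {
  100 * lysis_with_competitor / lysis_reference
}

#' Score a table of clone recognition profiles
#'
#' @param profiles list of `CloneRecognitionProfile`s.
#' @param mode `"sum"` for the cross-reactivity score, `"count"` for the
#'   clone-count score.
#' @return named integer vector (an activity table usable by the QSAR
#'   functions).
#' @export
score_profiles <- function(profiles, mode = c("sum", "count")) {
  mode <- match.arg(mode)
  f <- if (mode == "sum") cross_reactivity_score else clone_count_score
  out <- vapply(profiles, f, numeric(1))
  names(out) <- vapply(profiles, function(p) p$peptide_id, character(1))
  out
}
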