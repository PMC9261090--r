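#' Ambivalence index for a positivity/negativity rating pair
#'
#' Quantifies co-activation of positive and negative affect for a single
#' stimulus as *total affect* (the mean of the positivity and negativity
#' ratings) minus *polarity* (their absolute difference):
#' \deqn{A = (P + N)/2 - |P - N|.}
#' The first term captures the strength of the joint response and
#' distinguishes co-activation from indifference; the second term removes
#' strong but polarized responses. On 0--8 rating scales the index ranges
#' from -4 (attained at ratings 8/0 or 0/8) to 8 (attained at 8/8); higher
#' values indicate more ambivalent responding.
#'
#' @param positivity,negativity numeric ratings in `[0, 8]` (vectorized;
#'   recycled to a common length).
#' @return Numeric vector of ambivalence values in `[-4, 8]`.
#' @seealso [ambivalence_components()] for the two constituent terms.
#' @examples
#' ambivalence(8, 2)  # strong but polarized: -1
#' ambivalence(5, 5)  # strong co-activation: 5
#' ambivalence(6, 0)  # same polarity as (8, 2), weaker total affect: -3
#' @export
ambivalence <- function(positivity, negativity) {
  check_rating(positivity, "positivity")
  check_rating(negativity, "negativity")
  (positivity + negativity) / 2 - abs(positivity - negativity)
}

#' Ambivalence index with its components
#'
#' @inheritParams ambivalence
#' @return A tibble with columns `total_affect` (mean of the two ratings),
#'   `polarity` (absolute rating difference) and `ambivalence`
#'   (`total_affect - polarity`).
#' @export
ambivalence_components <- function(positivity, negativity) {
  check_rating(positivity, "positivity")
  check_rating(negativity, "negativity")
  total <- (positivity + negativity) / 2
  pol <- abs(positivity - negativity)
  tibble::tibble(total_affect = total, polarity = pol,
                 ambivalence = total - pol)
}

#' Score a CAPE symptom scale
#'
#' Item-mean score for one scale of the Community Assessment of Psychic
#' Experiences (CAPE). Items are answered on a 1 ("never") to 4
#' ("nearly always") frequency scale; the scale score is the arithmetic
#' mean of its items, so it stays in `[1, 4]`. Missing or out-of-range
#' items are rejected rather than imputed (the instrument is administered
#' with forced entry, so a gap indicates a data handling error).
#'
#' @param items integer item responses, each in `{1, 2, 3, 4}`.
#' @return The mean item score (length-1 numeric).
#' @export
cape_scale_score <- function(items) {
  if (length(items) == 0) stop_validation("`items` must be non-empty")
  if (!is.numeric(items) || anyNA(items) || any(items != round(items)) ||
      any(items < 1 | items > 4)) {
    stop_validation("CAPE items must be integers in 1..4 with no missing values")
  }
  mean(items)
}

#' Score the Chapman anhedonia scales
#'
#' Sum score over the dichotomous (0 = disagree, 1 = agree) items of the
#' revised Chapman Physical and Social Anhedonia Scales (CAS). Physical and
#' social items are pooled into a single sum; the standard instrument has
#' 43 items, giving scores in `[0, 43]`.
#'
#' @param items binary item responses (0/1).
#' @param n_items expected number of items; set to `NULL` to skip the
#'   length check. Defaults to the standard 43.
#' @return Integer sum score.
#' @export
cas_score <- function(items, n_items = 43) {
  if (length(items) == 0) stop_validation("`items` must be non-empty")
  if (!is.numeric(items) || anyNA(items) || !all(items %in% c(0, 1))) {
    stop_validation("CAS items must be 0 or 1 with no missing values")
  }
  if (!is.null(n_items) && length(items) != n_items) {
    stop_validation("expected %d CAS items, got %d", n_items, length(items))
  }
  as.integer(sum(items))
}

#' Rescale symptom scores to a common range and center them
#'
#' Divides each score by the scale's possible maximum, so that instruments
#' with different metrics (CAPE item means in 1--4, CAS sums in 0--43) are
#' expressed on a comparable 0--1 range, then subtracts the sample mean of
#' the rescaled scores. Used before entering symptom scores as cross-level
#' moderators, so that moderator coefficients are comparable across scales
#' and main effects are evaluated at the sample-average symptom level.
#'
#' @param scores numeric vector of raw scale scores.
#' @param scale_max the scale's possible maximum (positive).
#' @return Numeric vector with sample mean 0; rank order is preserved.
#' @export
normalize_symptom_scores <- function(scores, scale_max) {
  if (length(scores) == 0) stop_validation("`scores` must be non-empty")
  if (!is.numeric(scale_max) || length(scale_max) != 1 || scale_max <= 0) {
    stop_validation("`scale_max` must be a single positive number")
  }
  if (!is.numeric(scores) || anyNA(scores)) {
    stop_validation("`scores` must be numeric with no missing values")
  }
  rescaled <- scores / scale_max
  rescaled - mean(rescaled)
}

#' Append normalized symptom scores to a participant table
#'
#' Adds `<scale>_norm` columns (unit-rescaled, sample-centered; see
#' [normalize_symptom_scores()]) for the four symptom scales.
#'
#' @param participants data frame with columns `cape_negative`,
#'   `cape_depression`, `cape_positive`, `cas_anhedonia`.
#' @return The input with four `_norm` columns appended (replaced if present).
#' @export
normalize_participants <- function(participants) {
  maxima <- symptom_scale_max()
  for (scale in symptom_scales()) {
    if (is.null(participants[[scale]])) {
      stop_validation("participant table lacks column `%s`", scale)
    }
    participants[[paste0(scale, "_norm")]] <-
      normalize_symptom_scores(participants[[scale]], maxima[[scale]])
  }
  participants
}

#' Standardized mean difference from summary statistics
#'
#' Cohen's d between two groups given their means and standard deviations,
#' using the unweighted root-mean-square of the two SDs as the denominator:
#' \eqn{d = (m_a - m_b) / \sqrt{(s_a^2 + s_b^2)/2}}. When both sample sizes
#' are supplied and `weighted = TRUE`, the classical n-weighted pooled SD
#' is used instead. Intended for comparing sample rating moments against
#' published normative moments when the norm-study sample size is unknown.
#'
#' @param mean_a,sd_a mean and SD of the first group (`sd_a > 0`).
#' @param mean_b,sd_b mean and SD of the second group (`sd_b > 0`).
#' @param n_a,n_b optional sample sizes, required for `weighted = TRUE`.
#' @param weighted use the n-weighted pooled SD.
#' @return Cohen's d (positive when `mean_a > mean_b`).
#' @examples
#' cohens_d(3.80, 2.40, 5.07, 2.34)  # about -0.54
#' @export
cohens_d <- function(mean_a, sd_a, mean_b, sd_b,
                     n_a = NULL, n_b = NULL, weighted = FALSE) {
  if (!all(vapply(list(mean_a, sd_a, mean_b, sd_b), is.numeric, logical(1)))) {
    stop_validation("means and SDs must be numeric")
  }
  if (sd_a <= 0 || sd_b <= 0) stop_validation("SDs must be positive")
  if (weighted) {
    if (is.null(n_a) || is.null(n_b)) {
      stop_validation("`n_a` and `n_b` are required when `weighted = TRUE`")
    }
    pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  } else {
    pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  }
  (mean_a - mean_b) / pooled
}
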