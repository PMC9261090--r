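#' Declare a random-effects structure
#'
#' Describes the random part of a mixed model: a by-subject intercept,
#' by-subject slopes over named design columns, a crossed by-stimulus
#' intercept, and whether by-subject terms share an unstructured covariance
#' or are independent (diagonal). Diagonal is the default: with discretized
#' 0--8 outcomes the correlation parameters are weakly identified and a
#' diagonal structure converges far more reliably.
#'
#' @param subject_intercept include `(1 | participant_id)`.
#' @param subject_slopes character vector of numeric design columns getting
#'   by-subject random slopes.
#' @param stimulus_intercept include `(1 | stimulus_id)`.
#' @param covariance `"diagonal"` (independent by-subject terms) or
#'   `"unstructured"` (freely correlated).
#' @return An object of class `esm_random`.
#' @export
random_structure <- function(subject_intercept = TRUE,
                             subject_slopes = character(0),
                             stimulus_intercept = TRUE,
                             covariance = c("diagonal", "unstructured")) {
  covariance <- match.arg(covariance)
  structure(list(subject_intercept = subject_intercept,
                 subject_slopes = subject_slopes,
                 stimulus_intercept = stimulus_intercept,
                 covariance = covariance),
            class = "esm_random")
}

new_esm_design <- function(data, outcome, fixed, random, meta = list()) {
  structure(c(list(data = tibble::as_tibble(data), outcome = outcome,
                   fixed = fixed, random = random), meta),
            class = "esm_design")
}

#' @export
print.esm_design <- function(x, ...) {
  cat("<esm_design>\n")
  cat(sprintf("  outcome: %s   rows: %d   participants: %d   stimuli: %d\n",
              x$outcome, nrow(x$data),
              length(unique(x$data$participant_id)),
              length(unique(x$data$stimulus_id))))
  cat(sprintf("  fixed:  %s ~ %s\n", x$outcome, x$fixed))
  slopes <- if (length(x$random$subject_slopes)) {
    paste(x$random$subject_slopes, collapse = ", ")
  } else "none"
  cat(sprintf("  random: subject intercept %s, subject slopes: %s, stimulus intercept %s (%s)\n",
              x$random$subject_intercept, slopes,
              x$random$stimulus_intercept, x$random$covariance))
  if (!is.null(x$moderator)) cat(sprintf("  moderator: %s\n", x$moderator))
  invisible(x)
}

# Validate a trial table on entry to a design builder. Rating-scale data
# go through the strict integer validator; continuous wide-scale synthetic
# trials (attribute "continuous", produced by simulate_ratings() with
# discretize = FALSE) keep their real-valued ratings and are only checked
# for structure.
validate_for_design <- function(trials) {
  if (isTRUE(attr(trials, "continuous"))) {
    needed <- c("participant_id", "stimulus_id", "category", "social",
                "positivity", "negativity", "arousal")
    missing_cols <- setdiff(needed, names(trials))
    if (length(missing_cols) > 0) {
      stop_validation("trial table lacks columns: %s",
                      paste(missing_cols, collapse = ", "))
    }
    trials <- tibble::as_tibble(trials)[needed]
    trials$participant_id <- as.character(trials$participant_id)
    trials$stimulus_id <- as.character(trials$stimulus_id)
    trials$category <- as_category(trials$category)
    if (anyNA(trials[c("positivity", "negativity", "arousal")])) {
      stop_validation("ratings must not contain missing values")
    }
    if (anyDuplicated(paste(trials$participant_id, trials$stimulus_id))) {
      stop_validation("duplicate participant x stimulus pair")
    }
    return(trials)
  }
  assemble_trial_table(trials)
}

# add numeric indicator columns used as by-subject random-slope carriers
add_category_dummies <- function(data) {
  data$cat_pleasant <- as.numeric(data$category == "pleasant")
  data$cat_unpleasant <- as.numeric(data$category == "unpleasant")
  data
}

#' Build the raw-response analysis dataset
#'
#' One row per trial; the chosen rating is the outcome and stimulus category
#' (neutral as reference level) is the fixed effect. The declared random
#' structure is maximal for this design: by-subject intercept, by-subject
#' category slopes, and a crossed by-stimulus intercept (stimuli are nested
#' in categories, so a plain by-stimulus intercept is the within-category
#' one).
#'
#' @param trials validated trial table (see [assemble_trial_table()]).
#' @param outcome `"positivity"`, `"negativity"` or `"arousal"`.
#' @return An `esm_design` object.
#' @export
build_category_design <- function(trials,
                                  outcome = c("positivity", "negativity",
                                              "arousal")) {
  outcome <- match.arg(outcome)
  trials <- validate_for_design(trials)
  if (length(unique(trials$category)) < 2) {
    warning("fewer than two stimulus categories present: no category contrast is estimable",
            call. = FALSE)
  }
  data <- add_category_dummies(trials)
  new_esm_design(
    data, outcome = outcome, fixed = "category",
    random = random_structure(subject_intercept = TRUE,
                              subject_slopes = c("cat_pleasant",
                                                 "cat_unpleasant"),
                              stimulus_intercept = TRUE)
  )
}

#' Build the ambivalence analysis dataset
#'
#' Identical in structure to [build_category_design()], but the outcome is
#' the per-trial ambivalence index computed from the positivity and
#' negativity ratings (see [ambivalence()]).
#'
#' @inheritParams build_category_design
#' @return An `esm_design` object with outcome `ambivalence`.
#' @export
build_ambivalence_design <- function(trials) {
  trials <- validate_for_design(trials)
  data <- add_category_dummies(trials)
  data$ambivalence <- ambivalence(data$positivity, data$negativity)
  new_esm_design(
    data, outcome = "ambivalence", fixed = "category",
    random = random_structure(subject_intercept = TRUE,
                              subject_slopes = c("cat_pleasant",
                                                 "cat_unpleasant"),
                              stimulus_intercept = TRUE)
  )
}

#' Build the activation-function dataset
#'
#' Restructures the trial table into the dataset from which the positivity
#' offset and negativity bias are estimated. The single outcome
#' `emotional_activation` collects, per participant, the positivity ratings
#' of all pleasant trials plus one random half of that participant's neutral
#' trials, and the negativity ratings of all unpleasant trials plus the
#' other half. The neutral set is partitioned randomly per participant, so
#' no stimulus contributes to both activation functions and a by-stimulus
#' random intercept remains meaningful; with an odd neutral count the
#' positivity side receives the larger half.
#'
#' Fixed predictors are the activation-function factor `fn` (levels
#' `negativity` — the reference — and `positivity`), arousal on its raw 0--8
#' coding, and their interaction; hence the `fn` main effect is the
#' positivity offset and the negated interaction is the negativity bias.
#' The declared random structure is by-subject random slopes for `fn` and
#' `fn x arousal` plus a by-stimulus intercept; no by-subject intercept,
#' since subject level differences in this design live on the function
#' contrast itself. The two by-subject slopes describe one latent
#' positivity function per subject (its level and its arousal response),
#' so they are allowed to covary freely: this design declares an
#' unstructured covariance, unlike the category designs. Forcing them
#' independent misallocates their covariance and understates both the
#' random-slope SDs and the precision of the offset.
#'
#' @inheritParams build_category_design
#' @param seed integer seed for the per-participant neutral split.
#' @return An `esm_design` object; the data carry numeric carriers
#'   `is_pos = [fn == positivity]` and `is_pos_arousal = is_pos * arousal`
#'   for the random slopes.
#' @export
build_activation_design <- function(trials, seed = 1) {
  trials <- validate_for_design(trials)
  n_neutral <- table(trials$participant_id[trials$category == "neutral"])
  ids <- unique(trials$participant_id)
  if (length(n_neutral) < length(ids) || any(n_neutral < 2)) {
    stop_validation("every participant needs at least 2 neutral trials for the random split")
  }
  with_seed(seed, {
    neutral <- trials[trials$category == "neutral", ]
    pos_mask <- logical(nrow(neutral))
    for (idx in split(seq_len(nrow(neutral)), neutral$participant_id)) {
      pos_mask[sample(idx, ceiling(length(idx) / 2))] <- TRUE
    }
    pos_rows <- rbind(trials[trials$category == "pleasant", ],
                      neutral[pos_mask, ])
    neg_rows <- rbind(trials[trials$category == "unpleasant", ],
                      neutral[!pos_mask, ])
    data <- rbind(
      tibble::tibble(participant_id = pos_rows$participant_id,
                     stimulus_id = pos_rows$stimulus_id,
                     category = pos_rows$category,
                     fn = "positivity",
                     arousal = pos_rows$arousal,
                     emotional_activation = pos_rows$positivity),
      tibble::tibble(participant_id = neg_rows$participant_id,
                     stimulus_id = neg_rows$stimulus_id,
                     category = neg_rows$category,
                     fn = "negativity",
                     arousal = neg_rows$arousal,
                     emotional_activation = neg_rows$negativity)
    )
    data$fn <- factor(data$fn, levels = c("negativity", "positivity"))
    data$is_pos <- as.numeric(data$fn == "positivity")
    data$is_pos_arousal <- data$is_pos * data$arousal
    new_esm_design(
      data, outcome = "emotional_activation", fixed = "fn * arousal",
      random = random_structure(subject_intercept = FALSE,
                                subject_slopes = c("is_pos",
                                                   "is_pos_arousal"),
                                stimulus_intercept = TRUE,
                                covariance = "unstructured")
    )
  })
}

# which other symptom scales enter as covariates for a given moderator:
# the remaining two symptom *areas* (negative, depression, positive); for
# the anhedonia moderator the negative-symptom scale is omitted because it
# overlaps conceptually with anhedonia.
moderator_covariate_scales <- function(moderator) {
  switch(moderator,
    cape_negative = c("cape_positive", "cape_depression"),
    cape_depression = c("cape_negative", "cape_positive"),
    cape_positive = c("cape_negative", "cape_depression"),
    cas_anhedonia = c("cape_positive", "cape_depression"),
    stop_validation("unknown moderator `%s`", moderator)
  )
}

#' Attach a level-2 symptom moderator to an analysis dataset
#'
#' Joins a participant-level moderator (the normalized, sample-centered
#' symptom score, re-centered on the participants actually present in the
#' design) to the trial rows, and extends the fixed-effect description so
#' the moderator interacts with every level-1 fixed term. With
#' `covariates = TRUE` (the default), age, a male-gender indicator, years of
#' education, and the normalized scores of the other two symptom areas
#' enter as main-effect covariates, all centered so that the level-1
#' coefficients remain interpretable at covariate means.
#'
#' @param design an `esm_design` from one of the builders.
#' @param moderator one of `"cape_negative"`, `"cape_depression"`,
#'   `"cape_positive"`, `"cas_anhedonia"`.
#' @param participants participant table carrying `_norm` symptom columns
#'   (see [normalize_participants()]) plus `age`, `gender`, `education`.
#' @param covariates include the covariate set (set `FALSE` for the
#'   covariate-free sensitivity configuration).
#' @return The design with column `mod` (and covariate columns) added, the
#'   fixed-effect description extended, and metadata `moderator` and
#'   `moderator_sd` (participant-level SD of `mod`, the step used for
#'   "-1 SD / mean / +1 SD" summaries).
#' @export
attach_moderator <- function(design, moderator, participants,
                             covariates = TRUE) {
  stopifnot(inherits(design, "esm_design"))
  moderator <- match.arg(moderator, symptom_scales())
  norm_col <- paste0(moderator, "_norm")
  need <- c("participant_id", "age", "gender", "education", norm_col,
            paste0(moderator_covariate_scales(moderator), "_norm"))
  missing_cols <- setdiff(need, names(participants))
  if (length(missing_cols) > 0) {
    stop_validation("participant table lacks columns: %s",
                    paste(missing_cols, collapse = ", "))
  }
  data <- design$data
  idx <- match(data$participant_id, participants$participant_id)
  if (anyNA(idx)) {
    stop_validation("trial rows reference participants missing from the participant table")
  }
  center_by_participant <- function(x) {
    x - mean(x[!duplicated(data$participant_id)])
  }
  data$mod <- center_by_participant(participants[[norm_col]][idx])
  fixed <- sprintf("(%s) * mod", design$fixed)
  covar_terms <- character(0)
  if (covariates) {
    data$age_c <- center_by_participant(participants$age[idx])
    data$male_c <- center_by_participant(
      as.numeric(participants$gender[idx] == "male"))
    data$education_c <- center_by_participant(participants$education[idx])
    covar_terms <- c("age_c", "male_c", "education_c")
    for (scale in moderator_covariate_scales(moderator)) {
      col <- paste0(scale, "_cov")
      data[[col]] <- center_by_participant(
        participants[[paste0(scale, "_norm")]][idx])
      covar_terms <- c(covar_terms, col)
    }
    fixed <- paste(c(fixed, covar_terms), collapse = " + ")
  }
  mod_sd <- stats::sd(data$mod[!duplicated(data$participant_id)])
  new_esm_design(data, outcome = design$outcome, fixed = fixed,
                 random = design$random,
                 meta = list(moderator = moderator, moderator_sd = mod_sd,
                             covariates = covariates,
                             base_fixed = design$fixed))
}

#' Serialize an analysis dataset
#'
#' Writes the long-format rows as CSV and the design description (outcome,
#' fixed-effect formula, random structure, moderator metadata) as a JSON
#' sidecar named `<path>.json`.
#'
#' @param design an `esm_design`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "esm_design"))
  utils::write.csv(design$data, path, row.names = FALSE)
  meta <- list(outcome = design$outcome, fixed = design$fixed,
               random = unclass(design$random),
               moderator = design$moderator,
               moderator_sd = design$moderator_sd)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
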