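#' Long-string careless-responding flag
#'
#' Flags a response stream when the longest run of consecutive identical
#' answers strictly exceeds `threshold` ("more than `threshold` similar
#' answers in a row"). Runs are counted over the answers in presentation
#' order; by default the questionnaire and task answers form one
#' concatenated stream, so a run may span the boundary between them.
#'
#' @param answers atomic vector of raw answer values in presentation order.
#' @param threshold run length above which the stream is flagged
#'   (strictly greater than; default 50).
#' @return `TRUE` if the participant should be excluded.
#' @export
long_string_flag <- function(answers, threshold = 50) {
  if (length(answers) == 0) stop_validation("`answers` must be non-empty")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1) {
    stop_validation("`threshold` must be a single integer >= 1")
  }
  if (anyNA(answers)) stop_validation("`answers` must not contain missing values")
  max(rle(as.vector(answers))$lengths) > threshold
}

#' Eligibility and data-quality filter for raw response streams
#'
#' Applies the study-level screening rules, in order: (1) participants with
#' incomplete questionnaires are excluded; (2) participants completing less
#' than `min_completion` of the rating task are excluded ("at least 75%" is
#' inclusive, so exactly 0.75 is kept); (3) among the remaining eligible
#' streams, long-string careless responders (see [long_string_flag()]) are
#' removed. Each exclusion is logged with its reason; the filter is
#' idempotent.
#'
#' @param streams data frame with columns `participant_id`,
#'   `task_completion` (fraction in `[0, 1]`), a list-column `answers`
#'   holding each participant's raw answer stream, and optionally
#'   `questionnaire_complete` (logical, assumed `TRUE` when absent).
#' @param min_completion minimum task completion fraction (inclusive).
#' @param long_string_threshold run-length threshold passed to
#'   [long_string_flag()]; `NULL` disables the long-string rule.
#' @return A list with `kept` (character vector of retained participant ids,
#'   in input order) and `excluded` (tibble with `participant_id`, `reason`).
#' @export
eligibility_filter <- function(streams, min_completion = 0.75,
                               long_string_threshold = 50) {
  if (min_completion <= 0 || min_completion > 1) {
    stop_validation("`min_completion` must be in (0, 1]")
  }
  if (nrow(streams) == 0) {
    return(list(kept = character(0),
                excluded = tibble::tibble(participant_id = character(0),
                                          reason = character(0))))
  }
  if (anyNA(streams$task_completion) ||
      any(streams$task_completion < 0 | streams$task_completion > 1)) {
    stop_validation("`task_completion` must lie in [0, 1]")
  }
  q_complete <- if (is.null(streams[["questionnaire_complete"]])) {
    rep(TRUE, nrow(streams))
  } else {
    streams$questionnaire_complete
  }
  reason <- rep(NA_character_, nrow(streams))
  reason[!q_complete] <- "incomplete_questionnaire"
  low <- is.na(reason) & streams$task_completion < min_completion
  reason[low] <- "task_completion_below_minimum"
  if (!is.null(long_string_threshold)) {
    eligible <- which(is.na(reason))
    flagged <- vapply(streams$answers[eligible], long_string_flag,
                      logical(1), threshold = long_string_threshold)
    reason[eligible[flagged]] <- "long_string"
  }
  keep <- is.na(reason)
  list(
    kept = as.character(streams$participant_id[keep]),
    excluded = tibble::tibble(
      participant_id = as.character(streams$participant_id[!keep]),
      reason = reason[!keep]
    )
  )
}

#' Assemble and validate a trial-level rating table
#'
#' Coerces raw trial rows into the validated long-format table used by all
#' design builders: one row per participant x stimulus with integer
#' positivity, negativity, and arousal ratings on the 0--8 scale, the
#' stimulus category, and the sociality flag. Out-of-range ratings and
#' duplicated participant x stimulus pairs are rejected with an error
#' naming the offending row.
#'
#' @param trials data frame with columns `participant_id`, `stimulus_id`,
#'   `category` (pleasant / neutral / unpleasant), `social` (logical),
#'   `positivity`, `negativity`, `arousal`.
#' @return A tibble with validated columns; `category` is a factor with
#'   neutral as reference level.
#' @export
assemble_trial_table <- function(trials) {
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
  trials$social <- as.logical(trials$social)
  for (col in c("positivity", "negativity", "arousal")) {
    x <- trials[[col]]
    bad <- which(is.na(x) | x < 0 | x > 8 | x != round(x))
    if (length(bad) > 0) {
      stop_validation("row %d: `%s` rating %s is not an integer in [0, 8]",
                      bad[1], col, format(x[bad[1]]))
    }
    trials[[col]] <- as.integer(x)
  }
  key <- paste(trials$participant_id, trials$stimulus_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_validation("row %d: duplicate participant x stimulus pair (%s, %s)",
                    dup[1], trials$participant_id[dup[1]],
                    trials$stimulus_id[dup[1]])
  }
  trials
}

#' Read / write trial tables as CSV
#'
#' Plain-CSV persistence for the long trial table (one row per participant x
#' stimulus). Reading re-validates through [assemble_trial_table()].
#'
#' @param path file path.
#' @param trials a validated trial table.
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  assemble_trial_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read / write participant tables as CSV
#'
#' One row per participant: `participant_id`, demographics (`age`, `gender`,
#' `education`), raw symptom scores (`cape_negative`, `cape_depression`,
#' `cape_positive`, `cas_anhedonia`) and, when present, their `_norm`
#' normalized counterparts. `read_participants()` recomputes the normalized
#' columns so they are always centered on the sample being read.
#'
#' @param path file path.
#' @param participants participant table.
#' @return `read_participants()` returns a tibble; `write_participants()`
#'   returns `path` invisibly.
#' @export
read_participants <- function(path) {
  normalize_participants(tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE)))
}

#' @rdname read_participants
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE)
  invisible(path)
}

#' Score item-level questionnaire responses
#'
#' Turns an item-level response table (one row per participant, one column
#' per item) into scale scores. CAPE items are scored by item mean per scale
#' ([cape_scale_score()]); CAS items by sum ([cas_score()]).
#'
#' @param items data frame with `participant_id` plus item columns.
#' @param scale_items named list mapping each of `cape_negative`,
#'   `cape_depression`, `cape_positive`, `cas_anhedonia` to the names of its
#'   item columns.
#' @return Tibble with `participant_id` and the four scale scores.
#' @export
score_questionnaire_items <- function(items, scale_items) {
  needed <- symptom_scales()
  if (!all(needed %in% names(scale_items))) {
    stop_validation("`scale_items` must name item columns for: %s",
                    paste(needed, collapse = ", "))
  }
  out <- tibble::tibble(participant_id = as.character(items$participant_id))
  for (scale in needed) {
    cols <- scale_items[[scale]]
    missing_cols <- setdiff(cols, names(items))
    if (length(missing_cols) > 0) {
      stop_validation("item columns not found: %s",
                      paste(missing_cols, collapse = ", "))
    }
    mat <- as.matrix(items[cols])
    scorer <- if (scale == "cas_anhedonia") {
      function(x) cas_score(x, n_items = length(cols))
    } else {
      cape_scale_score
    }
    out[[scale]] <- apply(mat, 1, scorer)
  }
  out
}
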