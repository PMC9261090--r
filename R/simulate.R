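#' Parameters for the synthetic rating-study generator
#'
#' Bundles every quantity the generator needs to emulate the structure of an
#' affective picture-rating study: sample and stimulus-set sizes, the
#' category-specific arousal distributions, the two linear activation
#' functions (positivity and negativity regressed on rated arousal), the
#' between-subject spread of the positivity offset and negativity bias,
#' symptom-scale marginal moments with a shared latent severity factor, and
#' cross-level moderation of offset and bias by that severity factor.
#'
#' The defaults describe a community sample of 261 participants rating 48
#' pictures (16 per category, half social per category) on 0--8 scales, with
#' activation-function intercepts 5.29 (positivity) and 2.89 (negativity),
#' slopes 0.01 and 0.42, a positivity offset of mean 2.40 and between-subject
#' SD 0.92, and a negativity bias of mean 0.41 and SD 0.17. Symptom scales
#' (three CAPE scales on 1--4, a 43-item anhedonia sum) load on one latent
#' severity factor with loading `sqrt(0.75)`, which reproduces pairwise CAPE
#' correlations near 0.75; severity moderates offset and bias with per-SD
#' coefficients `offset_mod` and `bias_mod`.
#'
#' Subject heterogeneity is placed on the offset and bias directly and
#' carried by the positivity function (the negativity function is common to
#' all subjects), so it is exactly the variation represented by an analysis
#' model whose by-subject random terms are the function contrast and its
#' interaction with arousal. The moderation share of the offset/bias
#' variance is
#' `offset_mod^2` (resp. `bias_mod^2`); the residual subject spread is
#' reduced accordingly, keeping the total between-subject SD at
#' `offset_sd` / `bias_sd`.
#'
#' @param n_participants number of participants.
#' @param n_pleasant,n_neutral,n_unpleasant stimuli per category.
#' @param prop_social proportion of social scenes within each category.
#' @param arousal_mean,arousal_sd named vectors (pleasant/neutral/unpleasant)
#'   of arousal-rating means and SDs on the 0--8 scale. The unpleasant mean
#'   defaults to 5.02 so that the unpleasant-minus-pleasant arousal contrast
#'   is 1.22 in expectation.
#' @param pos_intercept,pos_slope positivity activation function (intercept
#'   at arousal 0 and slope per arousal point).
#' @param neg_intercept,neg_slope negativity activation function.
#' @param offset_sd,bias_sd total between-subject SDs of the positivity
#'   offset and negativity bias (must be at least `|offset_mod|` /
#'   `|bias_mod|`).
#' @param offset_mod,bias_mod change in offset / bias per +1 SD of the
#'   latent symptom severity factor (negative values diminish both at
#'   higher severity).
#' @param pos_cat_shift,neg_cat_shift named vectors of additive category
#'   shifts applied to the continuous positivity / negativity responses on
#'   top of the activation functions. Defaults suppress positivity toward
#'   unpleasant scenes and negativity toward pleasant scenes while leaving
#'   the categories entering each activation function unshifted, so the
#'   generative activation structure is exactly the analysed one.
#' @param stimulus_sd SD of the by-stimulus intercept deviation (shared by
#'   both rating scales). The default 0.85 makes the generator reproduce
#'   the precision with which the activation-function intercepts and their
#'   difference are estimated at the full study size, where the stimulus
#'   term dominates the standard errors.
#' @param residual_sd SD of the trial-level rating noise. The default 1.6
#'   puts the observation-level SD of the activation outcome near 2.4, the
#'   value implied by the ratio of raw to standardized arousal-slope
#'   effects at the full study size.
#' @param symptom_mean,symptom_sd named vectors of marginal symptom-scale
#'   moments (CAPE item means, CAS sum).
#' @param symptom_loading loading of each scale on the latent severity
#'   factor, in `[0, 1]`; pairwise scale correlations are approximately
#'   `symptom_loading^2`.
#' @param cape_items named vector of item counts per CAPE scale (sets the
#'   granularity of discretized item-mean scores).
#' @param cas_items number of CAS items.
#' @param age_mean,age_sd,age_range,male_prop,edu_mean,edu_sd,edu_range
#'   demographic marginals.
#' @param discretize round ratings to integers and clip to `[0, 8]`
#'   (`TRUE`, the study's scale) or keep them continuous and unclipped
#'   (`FALSE`, useful for checking estimation consistency free of
#'   discretization distortion).
#' @return An object of class `esm_sim_params` (a validated list). The
#'   implied positivity offset (`pos_intercept - neg_intercept`) and
#'   negativity bias (`neg_slope - pos_slope`) are exposed as read-only
#'   elements `offset` and `bias`.
#' @export
esm_sim_params <- function(n_participants = 261,
                           n_pleasant = 16, n_neutral = 16, n_unpleasant = 16,
                           prop_social = 0.5,
                           arousal_mean = c(pleasant = 3.80, neutral = 2.87,
                                            unpleasant = 5.02),
                           arousal_sd = c(pleasant = 2.40, neutral = 1.93,
                                          unpleasant = 2.40),
                           pos_intercept = 5.29, pos_slope = 0.01,
                           neg_intercept = 2.89, neg_slope = 0.42,
                           offset_sd = 0.92, bias_sd = 0.17,
                           offset_mod = -0.8, bias_mod = -0.15,
                           pos_cat_shift = c(pleasant = 0, neutral = 0,
                                             unpleasant = -3.5),
                           neg_cat_shift = c(pleasant = -2, neutral = 0,
                                             unpleasant = 0),
                           stimulus_sd = 0.85, residual_sd = 1.6,
                           symptom_mean = c(cape_negative = 2.00,
                                            cape_depression = 1.94,
                                            cape_positive = 1.69,
                                            cas_anhedonia = 15.0),
                           symptom_sd = c(cape_negative = 0.57,
                                          cape_depression = 0.57,
                                          cape_positive = 0.61,
                                          cas_anhedonia = 8.13),
                           symptom_loading = sqrt(0.75),
                           cape_items = c(cape_negative = 14,
                                          cape_depression = 8,
                                          cape_positive = 20),
                           cas_items = 43,
                           age_mean = 41.3, age_sd = 13.7,
                           age_range = c(18, 75),
                           male_prop = 0.632,
                           edu_mean = 14.2, edu_sd = 5.0,
                           edu_range = c(0, 32),
                           discretize = TRUE) {
  p <- as.list(environment())
  cats <- c("pleasant", "neutral", "unpleasant")
  for (nm in c("arousal_mean", "arousal_sd", "pos_cat_shift", "neg_cat_shift")) {
    if (!all(cats %in% names(p[[nm]]))) {
      stop_validation("`%s` must be named for pleasant, neutral, unpleasant", nm)
    }
    p[[nm]] <- p[[nm]][cats]
  }
  if (any(c(p$n_pleasant, p$n_neutral, p$n_unpleasant) < 1)) {
    stop_validation("each stimulus category needs at least 1 stimulus")
  }
  sds <- c(p$arousal_sd, p$offset_sd, p$bias_sd, p$stimulus_sd, p$residual_sd,
           p$symptom_sd, p$age_sd, p$edu_sd)
  if (any(sds < 0)) stop_validation("all SDs must be >= 0")
  if (p$symptom_loading < 0 || p$symptom_loading > 1) {
    stop_validation("`symptom_loading` must lie in [0, 1]")
  }
  if (p$offset_sd < abs(p$offset_mod)) {
    stop_validation("`offset_sd` must be >= |offset_mod| (moderation share of the offset variance)")
  }
  if (p$bias_sd < abs(p$bias_mod)) {
    stop_validation("`bias_sd` must be >= |bias_mod|")
  }
  p$offset <- p$pos_intercept - p$neg_intercept
  p$bias <- p$neg_slope - p$pos_slope
  structure(p, class = "esm_sim_params")
}

#' @export
print.esm_sim_params <- function(x, ...) {
  cat("<esm_sim_params>\n")
  cat(sprintf("  %d participants, %d/%d/%d pleasant/neutral/unpleasant stimuli\n",
              x$n_participants, x$n_pleasant, x$n_neutral, x$n_unpleasant))
  cat(sprintf("  activation functions: positivity %.2f + %.2f a, negativity %.2f + %.2f a\n",
              x$pos_intercept, x$pos_slope, x$neg_intercept, x$neg_slope))
  cat(sprintf("  positivity offset %.2f (SD %.2f), negativity bias %.2f (SD %.2f)\n",
              x$offset, x$offset_sd, x$bias, x$bias_sd))
  cat(sprintf("  moderation per SD severity: offset %+.2f, bias %+.2f\n",
              x$offset_mod, x$bias_mod))
  invisible(x)
}

#' Read generator parameters from a YAML or JSON config file
#'
#' The file holds a flat mapping whose keys are [esm_sim_params()] argument
#' names; unknown keys are an error. Named-vector arguments are given as
#' mappings (e.g. `arousal_mean: {pleasant: 3.8, neutral: 2.87,
#' unpleasant: 5.02}`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `esm_sim_params` object.
#' @export
read_sim_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(esm_sim_params))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    stop_validation("unknown generator parameter(s): %s", paste(bad, collapse = ", "))
  }
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(esm_sim_params, raw)
}

#' Simulate a participant table
#'
#' Draws demographics from the configured marginals and the four symptom
#' scores from a one-factor latent Gaussian model: each scale is
#' `mean + sd * (loading * severity + sqrt(1 - loading^2) * unique)`, then
#' discretized to its instrument's granularity (CAPE item-mean steps, CAS
#' integer sums) and clipped to its valid range. The latent severity draw is
#' returned in column `.severity` (it is what moderates offset and bias in
#' [simulate_ratings()]); normalized `_norm` score columns are appended via
#' [normalize_participants()].
#'
#' @param params an [esm_sim_params()] object.
#' @param seed integer seed; identical seeds give identical tables.
#' @return Tibble, one row per participant.
#' @export
simulate_participants <- function(params, seed = 1) {
  stopifnot(inherits(params, "esm_sim_params"))
  with_seed(seed, {
    n <- params$n_participants
    id <- sprintf("P%03d", seq_len(n))
    age <- round(pmin(pmax(stats::rnorm(n, params$age_mean, params$age_sd),
                           params$age_range[1]), params$age_range[2]))
    gender <- ifelse(stats::runif(n) < params$male_prop, "male", "female")
    edu <- round(pmin(pmax(stats::rnorm(n, params$edu_mean, params$edu_sd),
                           params$edu_range[1]), params$edu_range[2]))
    severity <- stats::rnorm(n)
    lam <- params$symptom_loading
    uniq_sd <- sqrt(1 - lam^2)
    scores <- list()
    for (scale in symptom_scales()) {
      latent <- lam * severity + stats::rnorm(n, 0, uniq_sd)
      raw <- params$symptom_mean[[scale]] + params$symptom_sd[[scale]] * latent
      if (scale == "cas_anhedonia") {
        raw <- pmin(pmax(round(raw), 0), params$cas_items)
      } else {
        step <- 1 / params$cape_items[[scale]]
        raw <- pmin(pmax(round(raw / step) * step, 1), 4)
      }
      scores[[scale]] <- raw
    }
    out <- tibble::tibble(
      participant_id = id, age = age, gender = gender, education = edu,
      cape_negative = scores$cape_negative,
      cape_depression = scores$cape_depression,
      cape_positive = scores$cape_positive,
      cas_anhedonia = scores$cas_anhedonia,
      .severity = severity
    )
    normalize_participants(out)
  })
}

#' Simulate a stimulus set
#'
#' Builds the stimulus table: per-category counts, a sociality flag for the
#' configured proportion of each category, and a latent by-stimulus
#' intercept deviation (`N(0, stimulus_sd)`) that shifts both rating scales.
#'
#' @inheritParams simulate_participants
#' @return Tibble with `stimulus_id`, `category`, `social`,
#'   `stim_intercept`.
#' @export
simulate_stimulus_set <- function(params, seed = 1) {
  stopifnot(inherits(params, "esm_sim_params"))
  with_seed(seed, {
    counts <- c(pleasant = params$n_pleasant, neutral = params$n_neutral,
                unpleasant = params$n_unpleasant)
    category <- rep(names(counts), times = counts)
    n <- length(category)
    social <- unlist(lapply(counts, function(k) {
      n_soc <- round(params$prop_social * k)
      sample(rep(c(TRUE, FALSE), c(n_soc, k - n_soc)))
    }), use.names = FALSE)
    tibble::tibble(
      stimulus_id = sprintf("S%03d", seq_len(n)),
      category = as_category(category),
      social = social,
      stim_intercept = stats::rnorm(n, 0, params$stimulus_sd)
    )
  })
}

#' Simulate trial-level ratings
#'
#' For every participant x stimulus pair: draw the arousal rating from the
#' stimulus category's Gaussian (discretized to the 0--8 integer scale when
#' `params$discretize` is `TRUE`), then generate the positivity and
#' negativity ratings from the subject-specific activation functions
#' evaluated at that (discretized) arousal value, plus the category shift,
#' the by-stimulus intercept deviation, and Gaussian trial noise, finally
#' rounding and clipping to `[0, 8]`.
#'
#' Subject heterogeneity is placed on the positivity offset and negativity
#' bias directly — the quantities whose between-subject SDs the analysis
#' model estimates as random slopes — and carried entirely by the
#' positivity function (subject-specific positivity intercept and slope,
#' common negativity function). This makes the generator the exact
#' generative inverse of the analysis model, whose only by-subject random
#' terms are the function contrast and its interaction with arousal.
#' Offset and bias deviations are the sum of the latent-severity moderation
#' term (`offset_mod * .severity`, `bias_mod * .severity`) and an
#' independent residual whose SD tops the total up to `offset_sd` /
#' `bias_sd`.
#'
#' @param participants table from [simulate_participants()] (must carry
#'   `.severity`).
#' @param stimuli table from [simulate_stimulus_set()].
#' @inheritParams simulate_participants
#' @return Trial tibble (validated via [assemble_trial_table()] when
#'   discretized). Attributes: `clip_rate`, the proportion of positivity /
#'   negativity values altered by clipping to `[0, 8]`; `subject_truth`, a
#'   tibble of each subject's generating offset and bias.
#' @export
simulate_ratings <- function(participants, stimuli, params, seed = 1) {
  stopifnot(inherits(params, "esm_sim_params"))
  if (is.null(participants$.severity)) {
    stop_validation("`participants` must carry the `.severity` column from simulate_participants()")
  }
  with_seed(seed, {
    n_sub <- nrow(participants)
    n_stim <- nrow(stimuli)
    off_resid_sd <- sqrt(params$offset_sd^2 - params$offset_mod^2)
    bias_resid_sd <- sqrt(params$bias_sd^2 - params$bias_mod^2)
    offset_i <- params$offset + params$offset_mod * participants$.severity +
      stats::rnorm(n_sub, 0, off_resid_sd)
    bias_i <- params$bias + params$bias_mod * participants$.severity +
      stats::rnorm(n_sub, 0, bias_resid_sd)
    # subject deviations live on the positivity function: this is the exact
    # generative inverse of an analysis model whose only by-subject random
    # terms are the function contrast and its interaction with arousal
    p0_i <- params$pos_intercept + (offset_i - params$offset)
    n0_i <- rep(params$neg_intercept, n_sub)
    p1_i <- params$pos_slope - (bias_i - params$bias)
    n1_i <- rep(params$neg_slope, n_sub)

    sub_idx <- rep(seq_len(n_sub), each = n_stim)
    stim_idx <- rep(seq_len(n_stim), times = n_sub)
    cat_chr <- as.character(stimuli$category)[stim_idx]
    n_trial <- n_sub * n_stim

    arousal <- stats::rnorm(n_trial, unname(params$arousal_mean[cat_chr]),
                            unname(params$arousal_sd[cat_chr]))
    if (params$discretize) arousal <- pmin(pmax(round(arousal), 0), 8)

    mu_pos <- p0_i[sub_idx] + p1_i[sub_idx] * arousal +
      unname(params$pos_cat_shift[cat_chr]) + stimuli$stim_intercept[stim_idx]
    mu_neg <- n0_i[sub_idx] + n1_i[sub_idx] * arousal +
      unname(params$neg_cat_shift[cat_chr]) + stimuli$stim_intercept[stim_idx]
    pos <- mu_pos + stats::rnorm(n_trial, 0, params$residual_sd)
    neg <- mu_neg + stats::rnorm(n_trial, 0, params$residual_sd)

    clip_rate <- NA_real_
    if (params$discretize) {
      pos_r <- round(pos); neg_r <- round(neg)
      clip_rate <- mean(c(pos_r < 0 | pos_r > 8, neg_r < 0 | neg_r > 8))
      pos <- pmin(pmax(pos_r, 0), 8)
      neg <- pmin(pmax(neg_r, 0), 8)
    }

    trials <- tibble::tibble(
      participant_id = participants$participant_id[sub_idx],
      stimulus_id = stimuli$stimulus_id[stim_idx],
      category = as_category(cat_chr),
      social = stimuli$social[stim_idx],
      positivity = pos, negativity = neg, arousal = arousal
    )
    if (params$discretize) {
      trials <- assemble_trial_table(trials)
    } else {
      attr(trials, "continuous") <- TRUE
    }
    attr(trials, "clip_rate") <- clip_rate
    attr(trials, "subject_truth") <- tibble::tibble(
      participant_id = participants$participant_id,
      offset = offset_i, bias = bias_i
    )
    trials
  })
}

#' Simulate a complete synthetic rating study
#'
#' Convenience wrapper chaining [simulate_participants()],
#' [simulate_stimulus_set()] and [simulate_ratings()] under sub-seeds
#' derived from `seed`.
#'
#' @inheritParams simulate_participants
#' @return List with elements `participants`, `stimuli`, `trials`, `params`.
#' @export
simulate_esm_study <- function(params = esm_sim_params(), seed = 1) {
  participants <- simulate_participants(params, seed = seed)
  stimuli <- simulate_stimulus_set(params, seed = seed + 1)
  trials <- simulate_ratings(participants, stimuli, params, seed = seed + 2)
  list(participants = participants, stimuli = stimuli, trials = trials,
       params = params)
}
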