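# Orchestration of the full analysis: raw-response models, ambivalence
# models, and the activation-function model from which the positivity
# offset and negativity bias are estimated, with cross-level symptom
# moderation; plus the parameter-recovery simulation harness.

# locate a fixed coefficient by its interaction components, robust to the
# order in which R names interaction terms
match_coef <- function(coef_names, components) {
  hit <- vapply(coef_names, function(nm) {
    setequal(strsplit(nm, ":", fixed = TRUE)[[1]], components)
  }, logical(1))
  which(hit)
}

coef_contrast <- function(fit, weights) {
  coefs <- names(lme4::fixef(fit$model))
  L <- numeric(length(coefs))
  for (nm in names(weights)) {
    idx <- match_coef(coefs, strsplit(nm, ":", fixed = TRUE)[[1]])
    if (length(idx) != 1) {
      stop_validation("coefficient `%s` not found in the model", nm)
    }
    L[idx] <- weights[[nm]]
  }
  L
}

ranef_sd <- function(fit, term) {
  hit <- fit$ranef$group == "participant_id" & fit$ranef$term == term
  if (!any(hit)) return(NA_real_)
  fit$ranef$sd[hit][1]
}

anova_p <- function(fit, components) {
  if (is.null(fit$anova)) return(NA_real_)
  hit <- vapply(fit$anova$term, function(nm) {
    setequal(strsplit(nm, ":", fixed = TRUE)[[1]], components)
  }, logical(1))
  if (!any(hit)) return(NA_real_)
  fit$anova$`Pr(>F)`[hit][1]
}

beta_of <- function(fit, components) {
  idx <- match_coef(fit$coefs$term, components)
  if (length(idx) != 1) return(NA_real_)
  fit$coefs$beta[idx]
}

#' Positivity offset and negativity bias from an activation-function fit
#'
#' Extracts the Evaluative Space Model quantities from a fitted
#' activation-function model (see [build_activation_design()]): the two
#' function intercepts and arousal slopes, the positivity offset (the
#' activation-function main effect, identically the intercept difference),
#' the negativity bias (the negated function-by-arousal interaction,
#' identically the slope difference), their between-subject SDs (the
#' corresponding random-slope SDs), and full inference (Satterthwaite df,
#' 95% CI, standardized beta) for each quantity.
#'
#' @param fit an `esm_fit` of an activation design (base or moderated; for
#'   a moderated fit all quantities are evaluated at the sample-mean
#'   moderator and covariates, which are centered).
#' @return A tibble with one row per quantity (`pos_intercept`,
#'   `neg_intercept`, `offset`, `pos_slope`, `neg_slope`, `bias`) and
#'   columns `estimate`, `se`, `df`, `t`, `p`, `ci_lower`, `ci_upper`,
#'   `beta`, `subject_sd` (NA where no random term corresponds).
#' @export
offset_bias_estimates <- function(fit) {
  stopifnot(inherits(fit, "esm_fit"))
  contrasts <- list(
    neg_intercept = c("(Intercept)" = 1),
    pos_intercept = c("(Intercept)" = 1, "fnpositivity" = 1),
    offset = c("fnpositivity" = 1),
    neg_slope = c("arousal" = 1),
    pos_slope = c("arousal" = 1, "fnpositivity:arousal" = 1),
    bias = c("fnpositivity:arousal" = -1)
  )
  rows <- lapply(names(contrasts), function(q) {
    inf <- contrast_inference(fit, coef_contrast(fit, contrasts[[q]]))
    cbind(tibble::tibble(quantity = q), inf)
  })
  out <- dplyr::bind_rows(rows)
  # standardized beta only for single-coefficient quantities (sign carried)
  out$beta <- c(NA_real_, NA_real_, beta_of(fit, "fnpositivity"), NA_real_,
                NA_real_, -beta_of(fit, c("fnpositivity", "arousal")))
  out$subject_sd <- c(NA_real_, NA_real_, ranef_sd(fit, "is_pos"), NA_real_,
                      NA_real_, ranef_sd(fit, "is_pos_arousal"))
  out
}

#' Run the positivity offset / negativity bias analysis
#'
#' Fits the base activation-function model, then (optionally) one moderated
#' model per symptom scale, and assembles: base offset/bias estimates with
#' tests and between-subject SDs, conditional arousal slopes within each
#' activation function, and for every moderator the
#' function-by-moderator and function-by-arousal-by-moderator interaction
#' tests (Bonferroni-corrected within the four-moderator family) plus the
#' offset and bias evaluated at -1 SD, the mean, and +1 SD of the
#' normalized moderator.
#'
#' @param trials validated trial table.
#' @param participants participant table with normalized symptom scores.
#' @param moderators symptom scales to analyse as moderators (default all
#'   four; use `character(0)` for the base model only).
#' @param covariates include age, gender, education and the other symptom
#'   areas as covariates in moderated models.
#' @param seed seed for the random per-participant neutral split.
#' @param random optional [random_structure()] override.
#' @return An object of class `esm_estimates`: list with `base`
#'   (fit + estimate table + conditional arousal slopes), `moderated`
#'   (per-moderator fit, interaction tests, evaluation grid), and `table`
#'   (the assembled offset/bias-by-symptom-level summary table).
#' @export
run_offset_bias_analysis <- function(trials, participants,
                                     moderators = symptom_scales(),
                                     covariates = TRUE, seed = 1,
                                     random = NULL) {
  design <- build_activation_design(trials, seed = seed)
  base_fit <- fit_lmm(design, random = random)
  base_est <- offset_bias_estimates(base_fit)
  arousal_cond <- conditional_effects(base_fit, effect = "arousal",
                                      within = "fn", force = TRUE)
  moderated <- list()
  grid_rows <- list()
  effect_rows <- list()
  for (m in moderators) {
    d_m <- attach_moderator(design, m, participants, covariates = covariates)
    fit_m <- fit_lmm(d_m, random = random)
    sd_m <- d_m$moderator_sd
    grid <- dplyr::bind_rows(lapply(
      c(`-1 SD` = -1, Mean = 0, `+1 SD` = 1), function(z) {
        off_L <- coef_contrast(fit_m, stats::setNames(
          c(1, z * sd_m), c("fnpositivity", "fnpositivity:mod")))
        bias_L <- coef_contrast(fit_m, stats::setNames(
          c(-1, -z * sd_m),
          c("fnpositivity:arousal", "fnpositivity:arousal:mod")))
        off <- contrast_inference(fit_m, off_L)
        bia <- contrast_inference(fit_m, bias_L)
        tibble::tibble(offset = off$estimate, offset_ci_lower = off$ci_lower,
                       offset_ci_upper = off$ci_upper, offset_p = off$p,
                       bias = bia$estimate, bias_ci_lower = bia$ci_lower,
                       bias_ci_upper = bia$ci_upper, bias_p = bia$p)
      }), .id = "level")
    grid <- cbind(tibble::tibble(moderator = m), grid)
    int_offset_p <- anova_p(fit_m, c("fn", "mod"))
    int_bias_p <- anova_p(fit_m, c("fn", "arousal", "mod"))
    eff <- tibble::tibble(
      moderator = m,
      target = c("offset", "bias"),
      # per-SD change of the target with the moderator
      estimate_per_sd = c(
        fit_m$coefs$estimate[match_coef(fit_m$coefs$term, c("fnpositivity", "mod"))] * sd_m,
        -fit_m$coefs$estimate[match_coef(fit_m$coefs$term, c("fnpositivity", "arousal", "mod"))] * sd_m),
      beta = c(beta_of(fit_m, c("fnpositivity", "mod")),
               -beta_of(fit_m, c("fnpositivity", "arousal", "mod"))),
      p = c(int_offset_p, int_bias_p)
    )
    moderated[[m]] <- list(fit = fit_m, grid = grid,
                           interaction_p = c(offset = int_offset_p,
                                             bias = int_bias_p),
                           moderator_sd = sd_m)
    grid_rows[[m]] <- grid
    effect_rows[[m]] <- eff
  }
  effects <- dplyr::bind_rows(effect_rows)
  if (nrow(effects) > 0) {
    # family = the moderator interaction tests for one target quantity
    effects$p_bonferroni <- NA_real_
    for (target in unique(effects$target)) {
      sel <- effects$target == target
      effects$p_bonferroni[sel] <-
        bonferroni_adjust(effects$p[sel], family_size = length(moderators))
    }
  }
  structure(list(
    base = list(fit = base_fit, estimates = base_est,
                arousal_conditional = arousal_cond),
    moderated = moderated,
    table = dplyr::bind_rows(grid_rows),
    effects = effects,
    seed = seed
  ), class = "esm_estimates")
}

#' @export
print.esm_estimates <- function(x, digits = 3, ...) {
  cat("<esm_estimates>\n")
  est <- x$base$estimates
  off <- est[est$quantity == "offset", ]
  bia <- est[est$quantity == "bias", ]
  cat(sprintf("  positivity offset %.2f (subject SD %.2f), 95%% CI [%.2f, %.2f], t(%.1f) = %.2f\n",
              off$estimate, off$subject_sd, off$ci_lower, off$ci_upper,
              off$df, off$t))
  cat(sprintf("  negativity bias   %.2f (subject SD %.2f), 95%% CI [%.2f, %.2f], t(%.1f) = %.2f\n",
              bia$estimate, bia$subject_sd, bia$ci_lower, bia$ci_upper,
              bia$df, bia$t))
  if (nrow(x$table) > 0) {
    cat("  offset/bias by symptom level:\n")
    print(as.data.frame(x$table[c("moderator", "level", "offset", "bias")]),
          digits = digits)
  }
  invisible(x)
}

run_category_family <- function(design_fun, trials, participants, moderators,
                                covariates, random) {
  base_design <- design_fun(trials)
  base_fit <- fit_lmm(base_design, random = random)
  pairwise <- dplyr::bind_rows(
    pleasant_vs_neutral = contrast_inference(
      base_fit, coef_contrast(base_fit, c(categorypleasant = 1))),
    unpleasant_vs_neutral = contrast_inference(
      base_fit, coef_contrast(base_fit, c(categoryunpleasant = 1))),
    pleasant_vs_unpleasant = contrast_inference(
      base_fit, coef_contrast(base_fit, c(categorypleasant = 1,
                                          categoryunpleasant = -1))),
    .id = "contrast")
  sd_y <- stats::sd(base_design$data[[base_design$outcome]])
  pairwise$beta <- pairwise$estimate / sd_y
  moderated <- list()
  for (m in moderators) {
    d_m <- attach_moderator(base_design, m, participants,
                            covariates = covariates)
    fit_m <- fit_lmm(d_m, random = random)
    moderated[[m]] <- list(
      fit = fit_m,
      interaction_p = anova_p(fit_m, c("category", "mod")),
      conditional = conditional_effects(fit_m, effect = "mod",
                                        within = "category")
    )
  }
  interaction_p <- vapply(moderated, function(x) x$interaction_p, numeric(1))
  list(fit = base_fit,
       omnibus_F = if (!is.null(base_fit$anova)) {
         base_fit$anova[base_fit$anova$term == "category", ]
       } else NULL,
       pairwise = pairwise,
       moderated = moderated,
       interaction_p_bonferroni = if (length(interaction_p)) {
         bonferroni_adjust(interaction_p, family_size = length(moderators))
       } else numeric(0))
}

#' Run the raw emotional response analysis
#'
#' For each of positivity, negativity, and arousal: fits the base
#' category-difference model (omnibus F, all pairwise category contrasts
#' with standardized betas), then one moderated model per symptom scale
#' with the category-by-moderator interaction test (Bonferroni-corrected
#' within the four-moderator family per response variable) and, when the
#' interaction reaches trend level (p < 0.10), the conditional moderator
#' slopes within each category.
#'
#' @inheritParams run_offset_bias_analysis
#' @param outcomes which response variables to analyse.
#' @return A named list (one element per outcome), each as returned by the
#'   internal category-family runner: `fit`, `omnibus_F`, `pairwise`,
#'   `moderated`, `interaction_p_bonferroni`.
#' @export
run_raw_response_analysis <- function(trials, participants,
                                      moderators = symptom_scales(),
                                      outcomes = c("positivity", "negativity",
                                                   "arousal"),
                                      covariates = TRUE, random = NULL) {
  out <- lapply(outcomes, function(oc) {
    run_category_family(function(tr) build_category_design(tr, outcome = oc),
                        trials, participants, moderators, covariates, random)
  })
  stats::setNames(out, outcomes)
}

#' Run the ambivalence analysis
#'
#' The category-difference and moderation analysis of
#' [run_raw_response_analysis()], applied to the per-trial ambivalence
#' index (see [ambivalence()]).
#'
#' @inheritParams run_offset_bias_analysis
#' @return One category-family result (see [run_raw_response_analysis()]).
#' @export
run_ambivalence_analysis <- function(trials, participants,
                                     moderators = symptom_scales(),
                                     covariates = TRUE, random = NULL) {
  run_category_family(build_ambivalence_design, trials, participants,
                      moderators, covariates, random)
}

#' Parameter-recovery simulation for the offset/bias estimator
#'
#' Repeatedly simulates a rating study from known generator parameters,
#' runs the activation-function analysis on each replicate, and summarises
#' how well the estimation pipeline recovers the generating positivity
#' offset, negativity bias, and function intercepts/slopes: mean estimate,
#' bias, RMSE, and empirical coverage of the 95% confidence intervals.
#'
#' @param params an [esm_sim_params()] object (typically at a reduced size,
#'   e.g. 60 participants and 8 stimuli per category).
#' @param n_reps number of replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param progress print a dot per replicate.
#' @return Object of class `esm_recovery`: `reps` (per-replicate estimates
#'   and CIs), `summary` (per-parameter recovery metrics), `params`.
#' @export
parameter_recovery <- function(params, n_reps = 100, seed = 1,
                               progress = FALSE) {
  stopifnot(inherits(params, "esm_sim_params"))
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 10L, n_reps))
  truth <- c(offset = params$offset, bias = params$bias,
             pos_intercept = params$pos_intercept,
             neg_intercept = params$neg_intercept,
             pos_slope = params$pos_slope, neg_slope = params$neg_slope)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    study <- simulate_esm_study(params, seed = rep_seeds[r])
    design <- build_activation_design(study$trials, seed = rep_seeds[r])
    fit <- fit_lmm(design)
    est <- offset_bias_estimates(fit)
    est$rep <- r
    est$singular <- fit$singular
    rows[[r]] <- est
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  reps <- dplyr::bind_rows(rows)
  reps$true <- truth[reps$quantity]
  summary <- dplyr::summarise(
    dplyr::group_by(reps, .data$quantity),
    true = .data$true[1],
    mean_estimate = mean(.data$estimate),
    bias = mean(.data$estimate - .data$true),
    rmse = sqrt(mean((.data$estimate - .data$true)^2)),
    coverage = mean(.data$ci_lower <= .data$true & .data$true <= .data$ci_upper),
    .groups = "drop")
  structure(list(reps = reps, summary = summary, params = params,
                 n_reps = n_reps, seed = seed),
            class = "esm_recovery")
}

#' @export
print.esm_recovery <- function(x, digits = 3, ...) {
  cat(sprintf("<esm_recovery> %d replicates, %d participants x %d stimuli\n",
              x$n_reps, x$params$n_participants,
              x$params$n_pleasant + x$params$n_neutral + x$params$n_unpleasant))
  print(as.data.frame(x$summary), digits = digits)
  invisible(x)
}

#' Serialize a recovery report
#'
#' @param recovery an `esm_recovery` object.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_recovery_json <- function(recovery, path) {
  stopifnot(inherits(recovery, "esm_recovery"))
  jsonlite::write_json(
    list(n_reps = recovery$n_reps, seed = recovery$seed,
         summary = recovery$summary, replicates = recovery$reps),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
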