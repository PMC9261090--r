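# Mixed-model estimation layer. Estimation itself is delegated to
# lme4/lmerTest (REML, Satterthwaite df); this layer owns formula
# construction from the declared design, the non-convergence
# simplification path, effect-size standardization, and reporting.

random_terms_formula <- function(random) {
  terms <- character(0)
  slopes <- random$subject_slopes
  if (random$covariance == "unstructured" && length(slopes) > 0) {
    lead <- if (random$subject_intercept) "1" else "0"
    terms <- c(terms, sprintf("(%s + %s | participant_id)", lead,
                              paste(slopes, collapse = " + ")))
  } else {
    if (random$subject_intercept) terms <- c(terms, "(1 | participant_id)")
    terms <- c(terms, sprintf("(0 + %s | participant_id)", slopes))
  }
  if (random$stimulus_intercept) terms <- c(terms, "(1 | stimulus_id)")
  terms
}

build_lmm_formula <- function(design, random) {
  rhs <- paste(c(design$fixed, random_terms_formula(random)), collapse = " + ")
  stats::as.formula(paste(design$outcome, "~", rhs))
}

fit_failed <- function(model) {
  if (is.null(model)) return(TRUE)
  conv <- model@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code != 0) return(TRUE)
  msgs <- unlist(conv$messages)
  any(grepl("failed to converge", msgs, ignore.case = TRUE))
}

try_lmer <- function(formula, data, reml) {
  tryCatch(
    suppressMessages(lmerTest::lmer(formula, data = data, REML = reml,
                                    control = lme4::lmerControl(
                                      optimizer = "bobyqa",
                                      optCtrl = list(maxfun = 100000),
                                      check.conv.singular = "ignore"))),
    error = function(e) structure(NULL, error = conditionMessage(e))
  )
}

#' Fit a linear mixed model for an analysis dataset
#'
#' Estimates the declared fixed effects and variance components by REML,
#' with crossed by-subject and by-stimulus random effects, and returns a
#' self-contained fit summary: per fixed effect the estimate, standard
#' error, Satterthwaite degrees of freedom, t, p, 95% CI and standardized
#' beta (`b * SD(x)/SD(y)` with observation-level SDs on the analysis
#' dataset); per random term its SD and variance (boundary estimates are
#' reported as 0, not suppressed); plus type-III omnibus F tests per fixed
#' factor.
#'
#' If the fit fails to converge, the random structure is simplified
#' automatically and each step is logged in `$simplifications`: an
#' unstructured covariance is first reduced to diagonal, then by-subject
#' random slopes are dropped one at a time (smallest estimated variance
#' first, last declared first when no estimate is available).
#'
#' @param design an `esm_design` from the design builders.
#' @param random optional [random_structure()] overriding the design's
#'   declared structure.
#' @param reml fit by REML (default) or ML.
#' @return An object of class `esm_fit`: a list with `coefs`, `ranef`,
#'   `anova`, `model` (the underlying `lmerModLmerTest` object), `formula`,
#'   `outcome`, `converged`, `singular`, `simplifications`, `reml_criterion`,
#'   `nobs` and design metadata (`moderator`, `moderator_sd`).
#' @export
fit_lmm <- function(design, random = NULL, reml = TRUE) {
  stopifnot(inherits(design, "esm_design"))
  random <- random %||% design$random
  stopifnot(inherits(random, "esm_random"))
  missing_slopes <- setdiff(random$subject_slopes, names(design$data))
  if (length(missing_slopes) > 0) {
    stop_validation("random slope column(s) not in the dataset: %s",
                    paste(missing_slopes, collapse = ", "))
  }
  if (length(unique(design$data$participant_id)) < 2 ||
      length(unique(design$data$stimulus_id)) < 2) {
    stop_validation("at least 2 participants and 2 stimuli are required")
  }

  simplifications <- character(0)
  current <- random
  model <- try_lmer(build_lmm_formula(design, current), design$data, reml)
  while (fit_failed(model)) {
    if (current$covariance == "unstructured") {
      current$covariance <- "diagonal"
      simplifications <- c(simplifications,
                           "covariance reduced to diagonal")
    } else if (length(current$subject_slopes) > 0) {
      drop <- if (!is.null(model)) {
        vc <- as.data.frame(lme4::VarCorr(model))
        vc <- vc[vc$grp != "Residual" & vc$var1 %in% current$subject_slopes &
                   is.na(vc$var2), ]
        if (nrow(vc) > 0) vc$var1[which.min(vc$vcov)] else
          utils::tail(current$subject_slopes, 1)
      } else {
        utils::tail(current$subject_slopes, 1)
      }
      current$subject_slopes <- setdiff(current$subject_slopes, drop)
      simplifications <- c(simplifications,
                           sprintf("dropped by-subject random slope `%s`", drop))
    } else {
      err <- attr(model, "error") %||% "convergence failure"
      stop(structure(class = c("esm_convergence_error", "error", "condition"),
                     list(message = sprintf(
                       "mixed model did not converge (%s); simplifications tried: %s",
                       err, paste(simplifications, collapse = "; ")),
                       call = NULL, simplifications = simplifications)))
    }
    model <- try_lmer(build_lmm_formula(design, current), design$data, reml)
  }

  y <- design$data[[design$outcome]]
  mm <- stats::model.matrix(model)
  summ <- summary(model)
  cf <- summ$coefficients
  df <- cf[, "df"]
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  crit <- stats::qt(0.975, df)
  beta <- standardized_beta_matrix(est, mm, y)
  coefs <- tibble::tibble(
    term = rownames(cf), estimate = unname(est), se = unname(se),
    df = unname(df), t = unname(cf[, "t value"]),
    p = unname(cf[, "Pr(>|t|)"]),
    ci_lower = unname(est - crit * se), ci_upper = unname(est + crit * se),
    beta = beta
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  ranef <- tibble::tibble(
    group = sub("\\.[0-9]+$", "", vc$grp),
    term = ifelse(is.na(vc$var1), "sd",
                  ifelse(is.na(vc$var2), vc$var1,
                         paste(vc$var1, vc$var2, sep = ":"))),
    sd = vc$sdcor, variance = vc$vcov
  )
  aov <- tryCatch(as.data.frame(stats::anova(model)),
                  error = function(e) NULL)
  structure(list(
    coefs = coefs, ranef = ranef,
    anova = if (!is.null(aov)) tibble::tibble(term = rownames(aov), aov) else NULL,
    model = model, formula = stats::formula(model),
    outcome = design$outcome,
    converged = !fit_failed(model), singular = lme4::isSingular(model),
    simplifications = simplifications,
    reml_criterion = as.numeric(lme4::REMLcrit(model)),
    nobs = nrow(design$data),
    moderator = design$moderator, moderator_sd = design$moderator_sd
  ), class = "esm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

standardized_beta_matrix <- function(est, mm, y) {
  sds <- apply(mm, 2, stats::sd)
  sy <- stats::sd(y)
  beta <- unname(est) * sds / sy
  zero_var <- sds == 0 & colnames(mm) != "(Intercept)"
  if (any(zero_var)) {
    warning("zero-variance predictor(s): standardized beta undefined, reported as NA",
            call. = FALSE)
    beta[zero_var] <- NA_real_
  }
  beta[colnames(mm) == "(Intercept)"] <- NA_real_
  unname(beta)
}

#' @export
print.esm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<esm_fit> %s (%d obs%s)\n", deparse(x$formula[[2]]), x$nobs,
              if (x$singular) ", singular fit" else ""))
  print(as.data.frame(x$coefs), digits = digits)
  cat("random-effect SDs:\n")
  print(as.data.frame(x$ranef), digits = digits)
  if (length(x$simplifications)) {
    cat("simplifications:", paste(x$simplifications, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Satterthwaite degrees of freedom for a fixed-effect contrast
#'
#' @param fit an `esm_fit`.
#' @param contrast either the name of a fixed-effect coefficient or a
#'   numeric contrast vector over the fixed coefficients.
#' @return Approximate (fractional) degrees of freedom. If the
#'   Satterthwaite computation fails, falls back to the residual rule
#'   `n - p` with a warning.
#' @export
approximate_df <- function(fit, contrast) {
  stopifnot(inherits(fit, "esm_fit"))
  L <- contrast_vector(fit, contrast)
  df <- tryCatch(lmerTest::contest1D(fit$model, L)$df,
                 error = function(e) NA_real_)
  if (is.na(df) || df <= 0) {
    warning("Satterthwaite computation failed; using residual df n - p",
            call. = FALSE)
    df <- fit$nobs - length(lme4::fixef(fit$model))
  }
  df
}

contrast_vector <- function(fit, contrast) {
  coefs <- names(lme4::fixef(fit$model))
  if (is.character(contrast)) {
    if (!contrast %in% coefs) {
      stop_validation("`%s` is not a fixed-effect coefficient", contrast)
    }
    L <- as.numeric(coefs == contrast)
  } else {
    if (length(contrast) != length(coefs)) {
      stop_validation("contrast length %d does not match %d fixed coefficients",
                      length(contrast), length(coefs))
    }
    L <- as.numeric(contrast)
  }
  L
}

# single-contrast inference: estimate, SE, Satterthwaite df, t, p, CI
contrast_inference <- function(fit, L) {
  res <- lmerTest::contest1D(fit$model, L, confint = TRUE)
  tibble::tibble(estimate = res$Estimate, se = res$`Std. Error`, df = res$df,
                 t = res$`t value`, p = res$`Pr(>|t|)`,
                 ci_lower = res$lower, ci_upper = res$upper)
}

#' Conditional (simple) effects of a predictor within factor levels
#'
#' Computes the slope of `effect` at each level of the factor `within`,
#' from a model containing the `within x effect` interaction: estimate,
#' Satterthwaite df, t, p, 95% CI, and standardized beta (the slope scaled
#' by `SD(effect)/SD(outcome)` on the analysis dataset). Following the
#' two-step reporting convention, the table is computed only when the
#' omnibus interaction reaches trend-level significance (p < 0.10) unless
#' `force = TRUE`; when suppressed, an empty table is returned with
#' attributes `suppressed = TRUE` and `interaction_p`.
#'
#' @param fit an `esm_fit` whose model contains `within` and `effect` fixed
#'   terms and their interaction.
#' @param effect name of the (numeric) predictor whose simple slopes are
#'   wanted, e.g. `"mod"` or `"arousal"`.
#' @param within name of the factor across whose levels the slope is
#'   evaluated, e.g. `"category"` or `"fn"`.
#' @param force compute the table regardless of the interaction p value.
#' @param trend_p threshold for the interaction gate (default 0.10).
#' @return Tibble with one row per level of `within`.
#' @export
conditional_effects <- function(fit, effect, within, force = FALSE,
                                trend_p = 0.10) {
  stopifnot(inherits(fit, "esm_fit"))
  frame <- stats::model.frame(fit$model)
  if (!within %in% names(frame) || !is.factor(frame[[within]])) {
    stop_validation("`within` must name a factor in the model (`%s` is not)",
                    within)
  }
  coefs <- names(lme4::fixef(fit$model))
  if (!effect %in% coefs) {
    stop_validation("`effect` must be a fixed-effect term (`%s` is not)", effect)
  }
  int_p <- interaction_p(fit, effect, within)
  if (is.na(int_p)) {
    stop_validation("model contains no `%s` x `%s` interaction", within, effect)
  }
  if (!force && int_p >= trend_p) {
    out <- tibble::tibble(level = character(0), estimate = numeric(0),
                          se = numeric(0), df = numeric(0), t = numeric(0),
                          p = numeric(0), ci_lower = numeric(0),
                          ci_upper = numeric(0), beta = numeric(0))
    attr(out, "suppressed") <- TRUE
    attr(out, "interaction_p") <- int_p
    return(out)
  }
  mm <- stats::model.matrix(fit$model)
  y <- stats::model.frame(fit$model)[[1]]
  sd_ratio <- stats::sd(mm[, effect]) / stats::sd(y)
  levels_w <- levels(frame[[within]])
  rows <- lapply(levels_w, function(lev) {
    L <- as.numeric(coefs == effect)
    dummy <- paste0(within, lev)
    two_way <- vapply(coefs, function(nm) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      length(parts) == 2 && setequal(parts, c(effect, dummy))
    }, logical(1))
    L <- L + as.numeric(two_way)
    cbind(tibble::tibble(level = lev), contrast_inference(fit, L))
  })
  out <- dplyr::bind_rows(rows)
  out$beta <- out$estimate * sd_ratio
  attr(out, "suppressed") <- FALSE
  attr(out, "interaction_p") <- int_p
  out
}

# omnibus p for the within:effect interaction from the type-III anova table
interaction_p <- function(fit, effect, within) {
  aov <- fit$anova
  if (is.null(aov)) return(NA_real_)
  hit <- vapply(aov$term, function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    length(parts) == 2 && setequal(parts, c(effect, within))
  }, logical(1))
  if (!any(hit)) return(NA_real_)
  aov$`Pr(>F)`[hit][1]
}

#' Standardized beta coefficients of a fit
#'
#' Returns `b * SD(x) / SD(y)` per fixed-effect column, with SDs taken at
#' observation level over the analysis dataset (the intercept has no beta).
#'
#' @param fit an `esm_fit`.
#' @return Named numeric vector.
#' @export
standardized_beta <- function(fit) {
  stopifnot(inherits(fit, "esm_fit"))
  stats::setNames(fit$coefs$beta, fit$coefs$term)
}

#' Bonferroni correction for a test family
#'
#' @param p_values p values in `[0, 1]`.
#' @param family_size size of the test family; must be at least the number
#'   of p values supplied (defaults to it).
#' @return Adjusted p values, `min(1, family_size * p)`.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_validation("p values must lie in [0, 1]")
  }
  if (family_size < length(p_values)) {
    stop_validation("`family_size` must be >= the number of tests")
  }
  stats::p.adjust(p_values, method = "bonferroni", n = family_size)
}

#' Serialize a fit
#'
#' `write_fit_tsv()` writes the fixed-effects table in reporting layout
#' (term, b, beta, 95% CI, t(df), p); `write_fit_json()` writes the full
#' fit summary (coefficients, random-effect SDs, omnibus tests,
#' convergence information).
#'
#' @param fit an `esm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "esm_fit"))
  tab <- fit$coefs
  out <- data.frame(
    term = tab$term,
    b = round(tab$estimate, 3),
    beta = round(tab$beta, 3),
    ci_95 = sprintf("[%.2f, %.2f]", tab$ci_lower, tab$ci_upper),
    t_df = sprintf("t(%.1f) = %.2f", tab$df, tab$t),
    p = signif(tab$p, 3)
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_tsv
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "esm_fit"))
  payload <- list(
    outcome = fit$outcome,
    formula = deparse1(fit$formula),
    coefficients = fit$coefs,
    random_effects = fit$ranef,
    anova = fit$anova,
    reml_criterion = fit$reml_criterion,
    converged = fit$converged,
    singular = fit$singular,
    simplifications = fit$simplifications,
    nobs = fit$nobs,
    moderator = fit$moderator
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
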