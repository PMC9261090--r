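test_that("the mixed model coincides with OLS when variance components vanish", {
  for (design in list(orthogonal_category_design("positivity"),
                      orthogonal_activation_design())) {
    fit <- suppressWarnings(fit_lmm(design))
    ols <- stats::lm(stats::reformulate(design$fixed, design$outcome),
                     data = design$data)
    expect_equal(fit$coefs$estimate, unname(stats::coef(ols)),
                 tolerance = 1e-6)
    expect_true(fit$singular)
  }
})

test_that("fixed effects on balanced data equal the closed-form cell means", {
  d <- orthogonal_category_design("positivity")
  fit <- suppressWarnings(fit_lmm(d))
  cell <- tapply(d$data$positivity, d$data$category, mean)
  expect_equal(fit$coefs$estimate[fit$coefs$term == "(Intercept)"],
               unname(cell["neutral"]), tolerance = 1e-8)
  expect_equal(fit$coefs$estimate[fit$coefs$term == "categorypleasant"],
               unname(cell["pleasant"] - cell["neutral"]), tolerance = 1e-8)
  expect_equal(fit$coefs$estimate[fit$coefs$term == "categoryunpleasant"],
               unname(cell["unpleasant"] - cell["neutral"]), tolerance = 1e-8)
})

test_that("Satterthwaite df matches the balanced one-way closed form", {
  fit <- fit_lmm(balanced_oneway_design(g = 8, n = 10))
  expect_equal(fit$coefs$df, 7, tolerance = 0.05)
  expect_equal(approximate_df(fit, "(Intercept)"), 7, tolerance = 0.05)
  fit12 <- fit_lmm(balanced_oneway_design(g = 12, n = 6, seed = 5))
  expect_equal(approximate_df(fit12, "(Intercept)"), 11, tolerance = 0.05)
})

test_that("df are positive, bounded by n - 1, and reject bad contrasts", {
  st <- tiny_study(seed = 301)
  fit <- suppressWarnings(fit_lmm(build_activation_design(st$trials, seed = 1)))
  expect_true(all(fit$coefs$df > 0))
  expect_true(all(fit$coefs$df <= fit$nobs - 1))
  expect_error(approximate_df(fit, "not_a_term"), "coefficient")
  expect_error(approximate_df(fit, c(1, 0)), "length")
})

test_that("estimates are invariant to row permutation and shift-equivariant", {
  st <- tiny_study(seed = 302)
  d <- build_category_design(st$trials, "negativity")
  f1 <- suppressWarnings(fit_lmm(d))
  set.seed(1)
  d_perm <- d
  d_perm$data <- d$data[sample(nrow(d$data)), ]
  f2 <- suppressWarnings(fit_lmm(d_perm))
  expect_equal(f1$coefs$estimate, f2$coefs$estimate, tolerance = 1e-6)
  expect_equal(f1$ranef$sd, f2$ranef$sd, tolerance = 1e-5)
  d_shift <- d
  d_shift$data$negativity <- d$data$negativity + 10
  f3 <- suppressWarnings(fit_lmm(d_shift))
  expect_equal(f3$coefs$estimate[f3$coefs$term == "(Intercept)"],
               f1$coefs$estimate[f1$coefs$term == "(Intercept)"] + 10,
               tolerance = 1e-5)
  expect_equal(f3$coefs$estimate[-1], f1$coefs$estimate[-1],
               tolerance = 1e-5)
  expect_equal(f3$ranef$sd, f1$ranef$sd, tolerance = 1e-4)
})

test_that("standardized beta is scale-invariant in the predictor", {
  st <- tiny_study(seed = 303)
  d <- build_activation_design(st$trials, seed = 1)
  f1 <- suppressWarnings(fit_lmm(d))
  d_k <- d
  d_k$data$arousal <- d$data$arousal / 4
  d_k$data$is_pos_arousal <- d_k$data$is_pos * d_k$data$arousal
  f2 <- suppressWarnings(fit_lmm(d_k))
  b1 <- f1$coefs[f1$coefs$term == "arousal", ]
  b2 <- f2$coefs[f2$coefs$term == "arousal", ]
  expect_equal(b2$estimate, b1$estimate * 4, tolerance = 1e-4)
  expect_equal(b2$beta, b1$beta, tolerance = 1e-4)
  betas <- standardized_beta(f1)
  expect_true(is.na(betas["(Intercept)"]))
  expect_equal(unname(betas["arousal"]), b1$beta)
})

test_that("confidence intervals bracket estimates and random SDs are non-negative", {
  st <- tiny_study(seed = 304)
  fit <- suppressWarnings(fit_lmm(build_ambivalence_design(st$trials)))
  expect_true(all(fit$coefs$ci_lower < fit$coefs$estimate))
  expect_true(all(fit$coefs$ci_upper > fit$coefs$estimate))
  expect_true(all(fit$ranef$sd >= 0))
  expect_true(all(c("participant_id", "stimulus_id", "Residual")
                  %in% fit$ranef$group))
})

test_that("conditional effects obey the exact coefficient identities", {
  st <- tiny_study(seed = 305)
  d <- attach_moderator(build_category_design(st$trials, "positivity"),
                        "cape_negative", st$participants)
  fit <- suppressWarnings(fit_lmm(d))
  ce <- conditional_effects(fit, effect = "mod", within = "category",
                            force = TRUE)
  expect_equal(ce$level, c("neutral", "pleasant", "unpleasant"))
  b <- stats::setNames(fit$coefs$estimate, fit$coefs$term)
  expect_equal(ce$estimate[ce$level == "neutral"], unname(b["mod"]),
               tolerance = 1e-10)
  expect_equal(ce$estimate[ce$level == "pleasant"],
               unname(b["mod"] + b["categorypleasant:mod"]),
               tolerance = 1e-10)
  expect_equal(ce$estimate[ce$level == "unpleasant"],
               unname(b["mod"] + b["categoryunpleasant:mod"]),
               tolerance = 1e-10)
  expect_error(conditional_effects(fit, effect = "mod", within = "social"),
               "factor")
})

test_that("the trend gate suppresses conditional effects for weak interactions", {
  # null-moderation generator: the category x moderator interaction is noise
  st <- tiny_study(seed = 306, offset_mod = 0, bias_mod = 0)
  d <- attach_moderator(build_category_design(st$trials, "arousal"),
                        "cape_positive", st$participants)
  fit <- suppressWarnings(fit_lmm(d))
  p_int <- evalspace:::interaction_p(fit, "mod", "category")
  ce <- conditional_effects(fit, effect = "mod", within = "category")
  if (p_int >= 0.10) {
    expect_equal(nrow(ce), 0)
    expect_true(attr(ce, "suppressed"))
    expect_equal(attr(ce, "interaction_p"), p_int)
  } else {
    expect_equal(nrow(ce), 3)
  }
  forced <- conditional_effects(fit, effect = "mod", within = "category",
                                force = TRUE)
  expect_equal(nrow(forced), 3)
})

test_that("Bonferroni adjustment caps at one and respects the family size", {
  expect_equal(bonferroni_adjust(0.01, family_size = 4), 0.04)
  expect_equal(bonferroni_adjust(0.4, family_size = 4), 1)
  expect_equal(bonferroni_adjust(c(0.03, 0.2)), c(0.06, 0.4))
  expect_equal(bonferroni_adjust(0.2, family_size = 1), 0.2)
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), family_size = 1), "family_size")
})

test_that("fits serialize to a reporting TSV and a full JSON summary", {
  st <- tiny_study(seed = 307)
  fit <- suppressWarnings(fit_lmm(build_category_design(st$trials, "positivity")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fit_tsv(fit, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(tab$term, fit$coefs$term)
  expect_true(all(c("b", "beta", "ci_95", "t_df", "p") %in% names(tab)))
  js <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$outcome, "positivity")
  expect_length(parsed$coefficients, nrow(fit$coefs))
})
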