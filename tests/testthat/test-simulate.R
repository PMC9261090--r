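test_that("generator parameters validate and expose derived offset and bias", {
  p <- esm_sim_params()
  expect_equal(p$offset, 2.40)
  expect_equal(p$bias, 0.41)
  expect_error(esm_sim_params(offset_sd = -1), "SD")
  expect_error(esm_sim_params(symptom_loading = 1.2), "loading")
  expect_error(esm_sim_params(offset_sd = 0.5, offset_mod = -0.8),
               "offset_sd")
  expect_error(esm_sim_params(n_pleasant = 0), "at least 1")
})

test_that("generator config files round-trip through YAML and JSON", {
  yf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_participants: 30", "residual_sd: 1.2",
               "arousal_mean: {pleasant: 4.0, neutral: 2.5, unpleasant: 5.0}"),
             yf)
  p <- read_sim_params(yf)
  expect_equal(p$n_participants, 30)
  expect_equal(unname(p$arousal_mean["pleasant"]), 4.0)
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_participants = 12, bias_sd = 0.2,
                            bias_mod = -0.1),
                       jf, auto_unbox = TRUE)
  expect_equal(read_sim_params(jf)$n_participants, 12)
  writeLines("nonsense_key: 3", yf)
  expect_error(read_sim_params(yf), "unknown generator parameter")
})

test_that("all three generators are deterministic under a fixed seed", {
  p <- tiny_params()
  expect_identical(simulate_participants(p, seed = 9),
                   simulate_participants(p, seed = 9))
  expect_identical(simulate_stimulus_set(p, seed = 9),
                   simulate_stimulus_set(p, seed = 9))
  s1 <- simulate_esm_study(p, seed = 9)
  s2 <- simulate_esm_study(p, seed = 9)
  expect_identical(s1$trials, s2$trials)
  expect_false(identical(simulate_participants(p, seed = 9),
                         simulate_participants(p, seed = 10)))
})

test_that("participant sample moments match the configured marginals", {
  part <- simulate_participants(esm_sim_params(), seed = 71)
  expect_equal(nrow(part), 261)
  expect_lt(abs(mean(part$cape_negative) - 2.00), 0.1)
  expect_lt(abs(sd(part$cape_negative) - 0.57), 0.1)
  expect_true(all(part$cape_negative >= 1 & part$cape_negative <= 4))
  expect_true(all(part$cas_anhedonia >= 0 & part$cas_anhedonia <= 43))
  expect_true(all(part$cas_anhedonia == round(part$cas_anhedonia)))
  # CAPE item-mean granularity: negative scale has 14 items
  expect_true(all(abs(part$cape_negative * 14 -
                        round(part$cape_negative * 14)) < 1e-9))
  expect_lt(abs(mean(part$cape_negative_norm)), 1e-12)
})

test_that("symptom scales share a severity factor with the configured strength", {
  p_null <- esm_sim_params(n_participants = 1000, symptom_loading = 0,
                           offset_mod = 0, bias_mod = 0)
  part0 <- simulate_participants(p_null, seed = 72)
  scales <- c("cape_negative", "cape_depression", "cape_positive",
              "cas_anhedonia")
  cors0 <- cor(part0[scales])
  expect_true(all(abs(cors0[upper.tri(cors0)]) < 0.1))
  part1 <- simulate_participants(
    esm_sim_params(n_participants = 1000), seed = 72)
  cape <- cor(part1[scales[1:3]])
  expect_true(all(cape[upper.tri(cape)] > 0.62 & cape[upper.tri(cape)] < 0.88))
})

test_that("the stimulus set has the configured census and sociality balance", {
  stim <- simulate_stimulus_set(esm_sim_params(), seed = 73)
  expect_equal(nrow(stim), 48)
  expect_equal(as.vector(table(stim$category, stim$social)[, "TRUE"]),
               c(8, 8, 8))
  small <- simulate_stimulus_set(
    esm_sim_params(n_pleasant = 2, n_neutral = 2, n_unpleasant = 2), seed = 73)
  expect_equal(nrow(small), 6)
  flat <- simulate_stimulus_set(esm_sim_params(stimulus_sd = 0), seed = 73)
  expect_true(all(flat$stim_intercept == 0))
})

test_that("the noise-free continuous limit reproduces the activation functions exactly", {
  p <- tiny_params(residual_sd = 0, stimulus_sd = 0, offset_sd = 0,
                   bias_sd = 0, offset_mod = 0, bias_mod = 0,
                   discretize = FALSE)
  st <- simulate_esm_study(p, seed = 74)
  pn <- st$trials[st$trials$category %in% c("pleasant", "neutral"), ]
  expect_equal(pn$positivity, 5.29 + 0.01 * pn$arousal, tolerance = 1e-12)
  un <- st$trials[st$trials$category %in% c("unpleasant", "neutral"), ]
  expect_equal(un$negativity, 2.89 + 0.42 * un$arousal, tolerance = 1e-12)
})

test_that("discretized ratings stay on the 0-8 grid with a bounded clip rate", {
  st <- simulate_esm_study(esm_sim_params(n_participants = 100), seed = 75)
  tr <- st$trials
  for (col in c("positivity", "negativity", "arousal")) {
    expect_true(all(tr[[col]] %in% 0:8))
  }
  expect_lt(attr(tr, "clip_rate"), 0.10)
  truth <- attr(tr, "subject_truth")
  expect_equal(nrow(truth), 100)
  expect_lt(abs(sd(truth$offset) - 0.92), 0.2)
})

test_that("category arousal means converge to their configured values", {
  p <- esm_sim_params(n_participants = 150)
  st <- simulate_esm_study(p, seed = 76)
  agg <- tapply(st$trials$arousal, st$trials$category, mean)
  # discretization to 0-8 pulls the unpleasant mean down slightly (mass
  # above 8 is clipped), so compare within 3 MC SEs plus a 0.1 clip margin
  for (cat in names(agg)) {
    n_cat <- sum(st$trials$category == cat)
    tol <- 3 * p$arousal_sd[[cat]] / sqrt(n_cat) + 0.1
    expect_lt(abs(agg[[cat]] - p$arousal_mean[[cat]]), tol)
  }
  expect_gt(agg[["unpleasant"]], agg[["pleasant"]])
})
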