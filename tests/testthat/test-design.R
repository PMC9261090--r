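test_that("category designs keep one row per trial with the declared structure", {
  st <- tiny_study(seed = 201)
  d <- build_category_design(st$trials, "arousal")
  expect_equal(nrow(d$data), nrow(st$trials))
  expect_equal(d$outcome, "arousal")
  expect_identical(d$data$arousal, st$trials$arousal)
  expect_equal(levels(d$data$category), c("neutral", "pleasant", "unpleasant"))
  expect_true(d$random$subject_intercept)
  expect_setequal(d$random$subject_slopes, c("cat_pleasant", "cat_unpleasant"))
  expect_error(build_category_design(st$trials, "ambivalence"))
  one_cat <- st$trials[st$trials$category == "pleasant", ]
  expect_warning(build_category_design(one_cat, "positivity"), "contrast")
})

test_that("the ambivalence design scores each trial and stays in bounds", {
  tr <- handmade_trials()
  d <- build_ambivalence_design(tr)
  expect_equal(d$outcome, "ambivalence")
  expect_equal(d$data$ambivalence[1], -1)  # ratings (8, 2)
  expect_true(all(d$data$ambivalence >= -4 & d$data$ambivalence <= 8))
  zero <- tr; zero$positivity <- 0L; zero$negativity <- 0L
  expect_true(all(build_ambivalence_design(zero)$data$ambivalence == 0))
})

test_that("the activation design partitions neutral trials and duplicates nothing", {
  st <- tiny_study(seed = 202)
  d <- build_activation_design(st$trials, seed = 7)
  dat <- d$data
  # one row per trial overall: pleasant + unpleasant + all neutral
  expect_equal(nrow(dat), nrow(st$trials))
  per_sub <- table(dat$participant_id)
  expect_true(all(per_sub == 12))
  # per participant: positivity side = pleasant + half the neutrals
  pos_side <- dat[dat$fn == "positivity", ]
  neg_side <- dat[dat$fn == "negativity", ]
  expect_true(all(table(pos_side$participant_id) == 4 + 2))
  expect_true(all(pos_side$category %in% c("pleasant", "neutral")))
  expect_true(all(neg_side$category %in% c("unpleasant", "neutral")))
  # neutral split is a partition per participant
  for (id in unique(dat$participant_id)[1:5]) {
    np <- pos_side$stimulus_id[pos_side$participant_id == id &
                                 pos_side$category == "neutral"]
    nn <- neg_side$stimulus_id[neg_side$participant_id == id &
                                 neg_side$category == "neutral"]
    expect_length(intersect(np, nn), 0)
    expect_setequal(c(np, nn),
                    unique(st$trials$stimulus_id[st$trials$category == "neutral"]))
  }
  # no stimulus under both functions for any participant
  expect_equal(anyDuplicated(paste(dat$participant_id, dat$stimulus_id)), 0)
  # outcome picks the side-appropriate rating
  merged <- merge(pos_side, st$trials,
                  by = c("participant_id", "stimulus_id"))
  expect_equal(merged$emotional_activation, merged$positivity)
})

test_that("the neutral split is seed-stable and handles odd counts", {
  st <- tiny_study(seed = 203)
  d1 <- build_activation_design(st$trials, seed = 7)
  d2 <- build_activation_design(st$trials, seed = 7)
  expect_identical(d1$data, d2$data)
  d3 <- build_activation_design(st$trials, seed = 8)
  expect_false(identical(d1$data, d3$data))
  odd <- tiny_study(seed = 204, n_neutral = 5)
  dodd <- build_activation_design(odd$trials, seed = 7)
  neu <- dodd$data[dodd$data$category == "neutral", ]
  counts <- table(neu$participant_id, neu$fn)
  expect_true(all(counts[, "positivity"] == 3))  # larger half
  expect_true(all(counts[, "negativity"] == 2))
  scarce <- st$trials[st$trials$category != "neutral", ]
  expect_error(build_activation_design(scarce, seed = 1), "neutral")
})

test_that("moderator attachment centers the moderator and adds the declared covariates", {
  st <- tiny_study(seed = 205)
  d <- build_activation_design(st$trials, seed = 1)
  dm <- attach_moderator(d, "cape_negative", st$participants)
  sub_rows <- !duplicated(dm$data$participant_id)
  expect_lt(abs(mean(dm$data$mod[sub_rows])), 1e-12)
  expect_equal(dm$moderator, "cape_negative")
  expect_true(all(c("age_c", "male_c", "education_c", "cape_positive_cov",
                    "cape_depression_cov") %in% names(dm$data)))
  expect_match(dm$fixed, "\\(fn \\* arousal\\) \\* mod")
  # anhedonia moderator controls for the positive and depression areas
  dcas <- attach_moderator(d, "cas_anhedonia", st$participants)
  expect_true(all(c("cape_positive_cov", "cape_depression_cov")
                  %in% names(dcas$data)))
  expect_false("cape_negative_cov" %in% names(dcas$data))
  bare <- attach_moderator(d, "cape_negative", st$participants,
                           covariates = FALSE)
  expect_false(any(c("age_c", "cape_positive_cov") %in% names(bare$data)))
  expect_equal(bare$fixed, "(fn * arousal) * mod")
  expect_error(attach_moderator(d, "phq9", st$participants), "arg")
})

test_that("designs serialize to CSV with a JSON sidecar", {
  st <- tiny_study(seed = 206)
  d <- build_activation_design(st$trials, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$outcome, "emotional_activation")
  expect_equal(meta$random$covariance, "unstructured")
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(d$data))
})
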