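# Shared fixtures, built in code at test time.

# a small but estimable synthetic study
tiny_params <- function(...) {
  args <- list(n_participants = 24, n_pleasant = 4, n_neutral = 4,
               n_unpleasant = 4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(esm_sim_params, args)
}

tiny_study <- function(seed = 101, ...) {
  simulate_esm_study(tiny_params(...), seed = seed)
}

# a handcrafted 2-participant x 4-stimulus trial table with known ratings
handmade_trials <- function() {
  tibble::tibble(
    participant_id = rep(c("a", "b"), each = 4),
    stimulus_id = rep(c("s1", "s2", "s3", "s4"), times = 2),
    category = rep(c("pleasant", "neutral", "neutral", "unpleasant"), 2),
    social = rep(c(TRUE, FALSE, TRUE, FALSE), 2),
    positivity = c(8, 5, 6, 0, 7, 4, 3, 1),
    negativity = c(2, 5, 0, 7, 1, 4, 2, 6),
    arousal = c(6, 3, 2, 7, 5, 2, 1, 8)
  )
}

# Balanced datasets whose residuals are exactly orthogonal to every random
# term, so REML variance components sit at the zero boundary and the mixed
# model must coincide with OLS: the zero-variance limit, realized exactly.
orthogonal_activation_design <- function() {
  n_sub <- 4
  rows <- expand.grid(sub = seq_len(n_sub), stim = 1:8)
  rows$fn <- ifelse(rows$stim <= 4, "positivity", "negativity")
  rows$arousal <- rep(c(2, 2, 5, 5), 2)[rows$stim]
  sgn <- (-1)^(rows$sub + rows$stim)
  rows$y <- 3 + 2 * (rows$fn == "positivity") + 0.4 * rows$arousal -
    0.3 * (rows$fn == "positivity") * rows$arousal + 0.6 * sgn
  d <- tibble::tibble(
    participant_id = sprintf("P%d", rows$sub),
    stimulus_id = sprintf("S%d", rows$stim),
    fn = factor(rows$fn, levels = c("negativity", "positivity")),
    arousal = rows$arousal,
    is_pos = as.numeric(rows$fn == "positivity")
  )
  d$is_pos_arousal <- d$is_pos * d$arousal
  d$emotional_activation <- rows$y
  evalspace:::new_esm_design(
    d, outcome = "emotional_activation", fixed = "fn * arousal",
    random = random_structure(FALSE, c("is_pos", "is_pos_arousal"), TRUE,
                              "unstructured"))
}

orthogonal_category_design <- function(outcome = "positivity") {
  n_sub <- 4
  rows <- expand.grid(sub = seq_len(n_sub), stim = 1:6)
  rows$category <- c("pleasant", "pleasant", "neutral", "neutral",
                     "unpleasant", "unpleasant")[rows$stim]
  sgn <- (-1)^(rows$sub + rows$stim)
  rows$y <- c(pleasant = 6, neutral = 4, unpleasant = 2)[rows$category] +
    0.5 * sgn
  d <- tibble::tibble(
    participant_id = sprintf("P%d", rows$sub),
    stimulus_id = sprintf("S%d", rows$stim),
    category = factor(rows$category,
                      levels = c("neutral", "pleasant", "unpleasant"))
  )
  d$cat_pleasant <- as.numeric(d$category == "pleasant")
  d$cat_unpleasant <- as.numeric(d$category == "unpleasant")
  d[[outcome]] <- rows$y
  evalspace:::new_esm_design(
    d, outcome = outcome, fixed = "category",
    random = random_structure(TRUE, c("cat_pleasant", "cat_unpleasant"),
                              TRUE))
}

# balanced one-way layout: Satterthwaite df of the grand mean has the
# closed form (number of groups - 1)
balanced_oneway_design <- function(g = 8, n = 10, seed = 4) {
  set.seed(seed)
  d <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", seq_len(g)), each = n),
    stimulus_id = rep(sprintf("S%02d", seq_len(n)), times = g),
    y = rep(stats::rnorm(g), each = n) + stats::rnorm(g * n, 0, 0.7)
  )
  evalspace:::new_esm_design(
    d, outcome = "y", fixed = "1",
    random = random_structure(TRUE, character(0), FALSE))
}
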