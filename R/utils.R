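# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_rating <- function(x, name = deparse(substitute(x)), max = 8) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_validation("`%s` must be numeric with no missing values", name)
  }
  if (any(x < 0 | x > max)) {
    bad <- which(x < 0 | x > max)[1L]
    stop_validation("`%s` must lie in [0, %s]; element %d is %s",
                    name, format(max), bad, format(x[bad]))
  }
  invisible(x)
}

# Ratings categories, in their display / reference order used throughout.
category_levels <- function() c("neutral", "pleasant", "unpleasant")

as_category <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), category_levels())
  if (length(bad) > 0) {
    stop_validation("unknown stimulus category: %s", paste(bad, collapse = ", "))
  }
  factor(x, levels = category_levels())
}

symptom_scales <- function() {
  c("cape_negative", "cape_depression", "cape_positive", "cas_anhedonia")
}

symptom_scale_max <- function() {
  c(cape_negative = 4, cape_depression = 4, cape_positive = 4, cas_anhedonia = 43)
}
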