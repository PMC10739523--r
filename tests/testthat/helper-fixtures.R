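## Shared fixtures, built in code at test time.

# Small cohort with planted signal used across modules.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_participants = 400, n_psychosocial = 60,
                           n_neural = 20, frac_nominal = 0.2,
                           frac_ordinal = 0.2, missing_rate_max = 0.4,
                           n_informative = 4, effect_size = 2,
                           sibling_rate = 0.15, seed = 42)
      cache <<- c(generate_cohort(cfg), list(config = cfg))
    }
    cache
  }
})

# Deterministic toy matrix with named columns.
toy_matrix <- function(n, p, seed = 1, prefix = "f") {
  set.seed(seed)
  matrix(stats::runif(n * p), n, p,
         dimnames = list(NULL, sprintf("%s%03d", prefix, seq_len(p))))
}

# A tiny linear "model" usable as a SHAP prediction function.
linear_predictor <- function(weights, intercept = 0) {
  function(x) intercept + as.vector(x[, names(weights), drop = FALSE] %*% weights)
}

expect_between <- function(object, lo, hi) {
  expect_gte(object, lo)
  expect_lte(object, hi)
}
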