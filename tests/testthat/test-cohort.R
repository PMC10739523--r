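test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_participants = 120, n_psychosocial = 30,
                       n_neural = 10, n_informative = 3, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(n_psychosocial = 2, n_neural = 2,
                             n_informative = 10), "exceeds")
  expect_error(cohort_config(missing_rate_max = 1.2), "missing_rate_max")
  expect_error(cohort_config(frac_nominal = 0.7, frac_ordinal = 0.7), "sum")
})

test_that("cohort has the documented structure", {
  g <- small_cohort()
  co <- g$cohort
  expect_s3_class(co, "iel_cohort")
  expect_true(all(co$participants$age_months >= 107 &
                    co$participants$age_months <= 132))
  expect_true(all(co$participants$sex %in% c("F", "M")))
  nr_cols <- co$feature_meta$feature[co$feature_meta$modality == "neural"]
  expect_false(anyNA(co$features[, nr_cols]))
  expect_length(g$ground_truth$informative_feature_ids, 4)
  expect_setequal(names(co$tscores),
                  c("pid", as.vector(outer(subscales(), c("_w1", "_w0"),
                                           paste0))))
})

test_that("wave-1 case prevalence at threshold 65 matches the normal tail", {
  cfg <- cohort_config(n_participants = 10000, n_psychosocial = 4,
                       n_neural = 2, n_informative = 2, missing_rate_max = 0,
                       sibling_rate = 0, seed = 99)
  co <- generate_cohort(cfg)$cohort
  prev <- mean(co$tscores$attention_w1 >= 65)
  expect_lt(abs(prev - (1 - pnorm(1.5))), 0.01)  # 6.68% +/- 1%
  # marginal T distribution ~ N(50, 10)
  expect_lt(abs(mean(co$tscores$attention_w1) - 50), 0.5)
  expect_lt(abs(sd(co$tscores$attention_w1) - 10), 0.5)
})

test_that("wave-0 and wave-1 scores correlate at the configured rho", {
  cfg <- cohort_config(n_participants = 6000, n_psychosocial = 4, n_neural = 2,
                       n_informative = 2, missing_rate_max = 0,
                       sibling_rate = 0, rho_waves = 0.5, seed = 3)
  co <- generate_cohort(cfg)$cohort
  r <- cor(co$tscores$aggressive_w0, co$tscores$aggressive_w1)
  expect_lt(abs(r - 0.5), 0.05)
})

test_that("zero effect size leaves every feature uncorrelated with case status", {
  cfg <- cohort_config(n_participants = 2500, n_psychosocial = 10,
                       n_neural = 5, n_informative = 3, effect_size = 0,
                       missing_rate_max = 0, sibling_rate = 0, seed = 17)
  g <- generate_cohort(cfg)
  y <- as.integer(g$cohort$tscores$attention_w1 >= 65)
  cont <- g$cohort$feature_meta$feature[g$cohort$feature_meta$type ==
                                          "continuous"]
  se <- 1 / sqrt(nrow(g$cohort$features) - 3)  # Fisher-z standard error
  cors <- abs(cor(g$cohort$features[, cont], y))
  expect_true(all(cors < 3 * se))
})

test_that("planted signal supports near-oracle discrimination at strong effect", {
  cfg <- cohort_config(n_participants = 3000, n_psychosocial = 20,
                       n_neural = 10, n_informative = 5, effect_size = 2,
                       missing_rate_max = 0, sibling_rate = 0, seed = 5)
  g <- generate_cohort(cfg)
  y <- as.integer(g$cohort$tscores$attention_w1 >= 65)
  x <- as.data.frame(g$cohort$features[, g$ground_truth$informative_feature_ids])
  train <- seq_len(2000)
  fit <- glm(y[train] ~ ., data = x[train, ], family = binomial())
  p <- predict(fit, newdata = x[-train, ], type = "response")
  auroc <- roc_points(p, y[-train])$auroc
  expect_gte(auroc, 0.85)
})

test_that("missingness injection is MCAR on psychosocial features only", {
  g <- small_cohort()
  co <- g$cohort
  meta <- co$feature_meta
  nr <- meta$feature[meta$modality == "neural"]
  ps <- meta$feature[meta$modality == "psychosocial"]
  expect_false(anyNA(co$features[, nr]))
  expect_true(anyNA(co$features[, ps]))
  # missing_rate_max > 0.35 plants at least one feature past the filter bound
  expect_true(any(colMeans(is.na(co$features[, ps])) > 0.35))
})

test_that("zero missing_rate_max leaves the cohort complete", {
  cfg <- cohort_config(n_participants = 100, n_psychosocial = 10, n_neural = 4,
                       n_informative = 2, missing_rate_max = 0, seed = 1)
  co <- generate_cohort(cfg)$cohort
  expect_false(anyNA(co$features))
})

test_that("per-feature missing rates are uniform on [0, missing_rate_max]", {
  cfg <- cohort_config(n_participants = 4000, n_psychosocial = 150,
                       n_neural = 2, n_informative = 2,
                       missing_rate_max = 0.5, sibling_rate = 0, seed = 23)
  co <- generate_cohort(cfg)$cohort
  ps <- co$feature_meta$feature[co$feature_meta$modality == "psychosocial"]
  rates <- colMeans(is.na(co$features[, ps]))
  ks <- suppressWarnings(ks.test(rates, "punif", 0, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("export and re-read round-trips the cohort exactly", {
  g <- small_cohort()
  dir <- withr::local_tempdir()
  export_cohort(g$cohort, g$ground_truth, dir)
  back <- read_cohort(dir)
  expect_equal(back$cohort$features, g$cohort$features)
  expect_equal(back$cohort$participants, g$cohort$participants)
  expect_equal(back$cohort$tscores, g$cohort$tscores)
  expect_setequal(back$ground_truth$informative_feature_ids,
                  g$ground_truth$informative_feature_ids)
  # missing entries serialized as empty fields and re-read as missing
  expect_identical(is.na(back$cohort$features), is.na(g$cohort$features))
  # ground-truth JSON lists exactly n_informative ids
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_length(gt$informative_feature_ids, 4)
})
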