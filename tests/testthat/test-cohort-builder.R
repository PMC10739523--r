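make_cohort_stub <- function(participants, tscores, n_feat = 3) {
  feat <- matrix(stats::rnorm(nrow(participants) * n_feat),
                 nrow(participants), n_feat,
                 dimnames = list(participants$pid,
                                 sprintf("ps%04d", seq_len(n_feat))))
  structure(list(
    participants = participants,
    features = feat,
    feature_meta = data.frame(feature = colnames(feat),
                              modality = "psychosocial", type = "continuous",
                              n_levels = NA_integer_,
                              stringsAsFactors = FALSE),
    tscores = tscores, config = NULL), class = "iel_cohort")
}

test_that("oldest sibling is kept, ties broken by smallest id", {
  p <- data.frame(pid = c("A", "B", "C", "D", "E"),
                  family_id = c("f1", "f1", "f2", "f3", "f3"),
                  age_months = c(120L, 118L, 110L, 115L, 115L),
                  sex = "F", stringsAsFactors = FALSE)
  ts <- data.frame(pid = p$pid, attention_w1 = 50, attention_w0 = 50,
                   aggressive_w1 = 50, aggressive_w0 = 50,
                   rule_breaking_w1 = 50, rule_breaking_w0 = 50)
  co <- make_cohort_stub(p, ts)
  expect_identical(select_unrelated(co), c("A", "C", "D"))
})

test_that("all singletons pass through unchanged", {
  g <- small_cohort()
  co <- g$cohort
  co$participants$family_id <- co$participants$pid
  expect_identical(select_unrelated(co), co$participants$pid)
})

test_that("train/test partition is disjoint, exhaustive and seeded", {
  ids <- sprintf("P%04d", 1:5356)
  pt <- partition_train_test(ids, 0.70, seed = 10)
  expect_length(pt$train, 3749)
  expect_length(pt$test, 1607)
  expect_length(intersect(pt$train, pt$test), 0)
  expect_setequal(c(pt$train, pt$test), ids)
  expect_identical(pt, partition_train_test(ids, 0.70, seed = 10))
  expect_false(identical(pt, partition_train_test(ids, 0.70, seed = 11)))
  pt2 <- partition_train_test(letters[1:10], 0.5, seed = 1)
  expect_length(pt2$train, 5)
  expect_error(partition_train_test(character(0)), "empty")
})

test_that("T-score discretization uses >= threshold and refuses missing", {
  expect_identical(discretize_tscore(c(65, 64.9, 70, 10)), c(1L, 0L, 1L, 0L))
  expect_error(discretize_tscore(c(65, NA)), "imputed")
})

test_that("new-onset labelling follows the truth table", {
  expect_identical(label_new_onset(c(0L, 1L, 0L, 1L), c(1L, 1L, 0L, 0L)),
                   c(1L, 0L, 0L, 0L))
})

test_that("case-control samples are balanced, matched and partition-local", {
  g <- small_cohort()
  ids <- select_unrelated(g$cohort)
  part <- partition_train_test(ids, 0.7, seed = 4)
  for (mode in c("new_onset", "prevailing")) {
    s <- build_case_control_sample(g$cohort,
                                   target_spec("attention", mode = mode),
                                   part)
    for (split in c("train", "test")) {
      y <- s[[split]]$y
      expect_equal(sum(y == 1), sum(y == 0))
    }
    expect_length(intersect(s$train$ids, s$test$ids), 0)
    m <- s$matching$train
    # every control matches its case's sex; reports carry age differences
    expect_true(all(m$sex == g$cohort$participants$sex[
      match(m$control, g$cohort$participants$pid)]))
    # control scores are below the case threshold, cases at/above
    expect_true(all(m$control_score < 65))
    expect_true(all(m$case_score >= 65))
    expect_lt(mean(m$control_score), mean(m$case_score))
  }
})

test_that("nearest-age same-sex control is selected", {
  p <- data.frame(pid = c("case1", "c118", "c121", "m119"),
                  family_id = paste0("f", 1:4),
                  age_months = c(119L, 118L, 121L, 119L),
                  sex = c("F", "F", "F", "M"), stringsAsFactors = FALSE)
  ts <- data.frame(pid = p$pid,
                   attention_w1 = c(80, 40, 41, 39), attention_w0 = 50,
                   aggressive_w1 = 50, aggressive_w0 = 50,
                   rule_breaking_w1 = 50, rule_breaking_w0 = 50)
  co <- make_cohort_stub(p, ts)
  part <- list(train = p$pid, test = p$pid)  # same tiny pool both sides
  s <- build_case_control_sample(co, target_spec("attention",
                                                 mode = "prevailing"), part)
  expect_identical(s$matching$train$control, "c118")
  expect_equal(s$matching$train$age_difference, -1L)
})

test_that("absence of cases raises a partition-naming error", {
  p <- data.frame(pid = c("a", "b"), family_id = c("f1", "f2"),
                  age_months = 120L, sex = "F", stringsAsFactors = FALSE)
  ts <- data.frame(pid = p$pid, attention_w1 = c(40, 41), attention_w0 = 50,
                   aggressive_w1 = 50, aggressive_w0 = 50,
                   rule_breaking_w1 = 50, rule_breaking_w0 = 50)
  co <- make_cohort_stub(p, ts)
  expect_error(build_case_control_sample(
    co, target_spec("attention", mode = "prevailing"),
    list(train = p$pid, test = p$pid)), "train")
})

test_that("six sample types are constructible from one cohort", {
  g <- small_cohort()
  ids <- select_unrelated(g$cohort)
  part <- partition_train_test(ids, 0.7, seed = 4)
  combos <- expand.grid(subscale = subscales(),
                        mode = c("new_onset", "prevailing"),
                        stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(combos)), function(i)
    build_case_control_sample(
      g$cohort, target_spec(combos$subscale[i], mode = combos$mode[i]), part))
  expect_length(samples, 6)
  expect_true(all(vapply(samples, inherits, TRUE, "experiment_sample")))
})
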