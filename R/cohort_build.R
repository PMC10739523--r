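#' Specify a predictive target
#'
#' A target is one CBCL-like syndrome subscale, a case threshold on the
#' follow-up T-score, and a case mode: `"new_onset"` (case at follow-up but
#' not at baseline) or `"prevailing"` (case at follow-up regardless of
#' baseline). T >= 65 is the borderline-clinical cut-point used to define
#' cases.
#'
#' @param subscale one of `"attention"`, `"aggressive"`, `"rule_breaking"`.
#' @param threshold case threshold on the T-score scale (default 65).
#' @param mode `"new_onset"` or `"prevailing"`.
#' @return a list of class `"target_spec"`.
#' @export
target_spec <- function(subscale = subscales(),
                        threshold = 65,
                        mode = c("new_onset", "prevailing")) {
  subscale <- match.arg(subscale)
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stopf("threshold must be a single positive number")
  structure(list(subscale = subscale, threshold = threshold, mode = mode),
            class = "target_spec")
}

#' Keep one participant per family
#'
#' Implements the unrelated-participant inclusion rule: if a family has
#' several enrolled children, the oldest (maximum `age_months`) is kept;
#' age ties are broken by the lexicographically smallest participant id.
#'
#' @param cohort an `"iel_cohort"`.
#' @return character vector of retained participant ids, in cohort order.
#' @export
select_unrelated <- function(cohort) {
  p <- cohort$participants
  ord <- order(p$family_id, -p$age_months, p$pid)
  keep <- p$pid[ord][!duplicated(p$family_id[ord])]
  p$pid[p$pid %in% keep]
}

#' Randomly partition participant ids into train and test sets
#'
#' The split is performed before any preprocessing or target thresholding.
#' The training set receives `floor(frac_train * n)` ids.
#'
#' @param ids participant ids.
#' @param frac_train training fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
partition_train_test <- function(ids, frac_train = 0.7, seed = 1L) {
  if (length(ids) == 0) stopf("cannot partition an empty id set")
  if (anyDuplicated(ids)) stopf("ids must be unique")
  if (!is.numeric(frac_train) || frac_train <= 0 || frac_train >= 1)
    stopf("frac_train must lie in (0, 1)")
  set.seed(seed)
  n_train <- floor(frac_train * length(ids))
  shuffled <- sample(ids)
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[-seq_len(n_train)]))
}

#' Discretize a T-score into case (1) / not-case (0)
#'
#' A participant is a case iff `T >= threshold`. Targets may not be imputed,
#' so missing scores are an error.
#'
#' @param T numeric vector of T-scores.
#' @param threshold case threshold (default 65).
#' @return integer vector of 0/1 labels.
#' @export
discretize_tscore <- function(T, threshold = 65) {
  if (any(!is.finite(T)))
    stopf("T-scores contain missing/non-finite values; targets may not be imputed")
  as.integer(T >= threshold)
}

#' New-onset label from baseline and follow-up case status
#'
#' 1 iff a participant is a case at follow-up (wave 1) and was not a case at
#' baseline (wave 0).
#'
#' @param case_w0,case_w1 binary vectors.
#' @return integer vector of 0/1 new-onset labels.
#' @export
label_new_onset <- function(case_w0, case_w1) {
  stopifnot(length(case_w0) == length(case_w1))
  as.integer(case_w1 == 1L & case_w0 == 0L)
}

case_labels_for <- function(cohort, target, ids) {
  ts <- cohort$tscores[match(ids, cohort$tscores$pid), , drop = FALSE]
  t1 <- ts[[paste0(target$subscale, "_w1")]]
  t0 <- ts[[paste0(target$subscale, "_w0")]]
  c1 <- discretize_tscore(t1, target$threshold)
  c0 <- discretize_tscore(t0, target$threshold)
  list(case_w0 = c0, case_w1 = c1,
       label = if (target$mode == "new_onset") label_new_onset(c0, c1) else c1,
       t1 = t1)
}

match_controls <- function(cases, pool, which_partition) {
  ## cases, pool: data.frames with pid, sex, age_months, score
  ## "lowest possible scores": restrict the pool, per sex, to the
  ## lowest-scoring candidates (exactly as many as there are cases of that
  ## sex), then match on age within that restricted pool
  keep <- logical(nrow(pool))
  for (sx in unique(cases$sex)) {
    need <- sum(cases$sex == sx)
    cand <- which(pool$sex == sx)
    cand <- cand[order(pool$score[cand], pool$pid[cand])]
    keep[utils::head(cand, need)] <- TRUE
  }
  pool <- pool[keep, , drop = FALSE]
  report <- vector("list", nrow(cases))
  avail <- rep(TRUE, nrow(pool))
  for (i in seq_len(nrow(cases))) {
    cand <- which(avail & pool$sex == cases$sex[i])
    if (length(cand) == 0)
      stopf("control pool exhausted in %s partition (no %s controls left)",
            which_partition, cases$sex[i])
    d_age <- abs(pool$age_months[cand] - cases$age_months[i])
    cand <- cand[d_age == min(d_age)]
    if (length(cand) > 1) {
      sc <- pool$score[cand]
      cand <- cand[sc == min(sc)]
      if (length(cand) > 1) cand <- cand[order(pool$pid[cand])][1]
    }
    avail[cand] <- FALSE
    report[[i]] <- data.frame(
      case = cases$pid[i], control = pool$pid[cand],
      sex = cases$sex[i],
      age_difference = pool$age_months[cand] - cases$age_months[i],
      control_score = pool$score[cand], case_score = cases$score[i],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, report)
}

#' Build a balanced, matched case-control experiment sample
#'
#' Within each partition independently, cases are participants meeting the
#' target definition; each case is matched to one control of the same sex
#' with the nearest age in months, drawn from the non-case pool with the
#' lowest follow-up scores on the target subscale (ties: lower score, then
#' smaller id). For new-onset targets the control pool is additionally
#' restricted to participants who are non-cases at both waves. The result is
#' a balanced sample with one control per case.
#'
#' @param cohort an `"iel_cohort"`.
#' @param target a [target_spec()].
#' @param partition list with `train`/`test` id vectors, as from
#'   [partition_train_test()].
#' @return a list of class `"experiment_sample"` with `train` and `test`
#'   (each: `x` raw feature matrix, `y` labels, `ids`), a per-partition
#'   `matching` report, and the target.
#' @export
build_case_control_sample <- function(cohort, target, partition) {
  stopifnot(inherits(cohort, "iel_cohort"), inherits(target, "target_spec"))
  build_one <- function(ids, which_partition) {
    lab <- case_labels_for(cohort, target, ids)
    p <- cohort$participants[match(ids, cohort$participants$pid), , drop = FALSE]
    info <- data.frame(pid = ids, sex = p$sex, age_months = p$age_months,
                       score = lab$t1, stringsAsFactors = FALSE)
    case_idx <- which(lab$label == 1L)
    if (length(case_idx) == 0)
      stopf("no %s cases of '%s' in %s partition",
            target$mode, target$subscale, which_partition)
    pool_ok <- lab$label == 0L
    if (target$mode == "new_onset")
      pool_ok <- pool_ok & lab$case_w1 == 0L & lab$case_w0 == 0L
    cases <- info[case_idx, , drop = FALSE]
    cases <- cases[order(cases$pid), , drop = FALSE]
    pool <- info[pool_ok, , drop = FALSE]
    matching <- match_controls(cases, pool, which_partition)
    sel <- c(matching$case, matching$control)
    y <- c(rep(1L, nrow(matching)), rep(0L, nrow(matching)))
    ord <- order(sel)
    sel <- sel[ord]; y <- y[ord]
    list(x = cohort$features[sel, , drop = FALSE],
         y = stats::setNames(y, sel),
         ids = sel, matching = matching)
  }
  tr <- build_one(partition$train, "train")
  te <- build_one(partition$test, "test")
  structure(list(
    train = tr[c("x", "y", "ids")],
    test = te[c("x", "y", "ids")],
    matching = list(train = tr$matching, test = te$matching),
    target = target
  ), class = "experiment_sample")
}

#' @export
print.experiment_sample <- function(x, ...) {
  cat(sprintf("Experiment sample: %s (%s, threshold %g)\n",
              x$target$subscale, x$target$mode, x$target$threshold))
  cat(sprintf("  train: %d rows (%d cases / %d controls)\n",
              length(x$train$y), sum(x$train$y == 1), sum(x$train$y == 0)))
  cat(sprintf("  test : %d rows (%d cases / %d controls)\n",
              length(x$test$y), sum(x$test$y == 1), sum(x$test$y == 0)))
  invisible(x)
}
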