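## End-to-end experiment orchestration: cohort -> case-control sample ->
## preprocessing -> coarse selection -> IEL-optimized deep network ->
## held-out evaluation and SHAP interpretation.

#' Configure the full pipeline
#'
#' Bundles the stage settings of one experiment run. `pipeline_config()`
#' gives study-scale defaults (population 100 evolutionary search, 3x300
#' network); [smoke_config()] gives a reduced configuration for fast
#' end-to-end runs.
#'
#' @param frac_train training fraction of the 70/30 partition.
#' @param threshold case threshold on the T-score scale.
#' @param max_missing missingness filter threshold.
#' @param nnmf_rank,nnmf_max_iter imputation settings.
#' @param eps_mi filter MI retention threshold.
#' @param alpha_range LASSO penalty search range.
#' @param lasso_iel [iel_config()] for the penalty search (or `NULL` for the
#'   compact default).
#' @param deep_iel [iel_config()] for the joint hyperparameter/feature
#'   search.
#' @param width,depth network architecture.
#' @param train a [train_config()].
#' @param param_mode BIC complexity term: `"n_features"` (pipeline default;
#'   see [cv_fitness()]) or `"full"`.
#' @param pool_cap cap on the fine-selection feature pool entering the joint
#'   deep-network search; when the LASSO selects more, the features with the
#'   largest absolute LASSO coefficients are kept. `Inf` (the study-scale
#'   default) passes every selected feature through; reduced-budget
#'   configurations cap the pool so the search density per feature stays
#'   comparable to the study's.
#' @param k_cap cross-validation fold cap.
#' @param cv_reps repeated cross-validation rounds per fitness evaluation
#'   (see [cv_fitness()]).
#' @param shap_samples permutations per explained row.
#' @param shap_background_n background set size.
#' @param shap_max_rows cap on explained test rows.
#' @param fit_on_train if `TRUE`, reuse training-partition preprocessing
#'   statistics on the test partition instead of refitting them there
#'   (default `FALSE`: each partition is preprocessed independently).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(frac_train = 0.7, threshold = 65,
                            max_missing = 0.35,
                            nnmf_rank = 8, nnmf_max_iter = 300,
                            eps_mi = 1e-6,
                            alpha_range = c(1e-4, 10),
                            lasso_iel = NULL,
                            deep_iel = iel_config(),
                            width = 300L, depth = 3L,
                            train = train_config(),
                            param_mode = c("n_features", "full"),
                            pool_cap = Inf,
                            k_cap = 20L,
                            cv_reps = 1L,
                            shap_samples = 16L,
                            shap_background_n = 100L,
                            shap_max_rows = 50L,
                            fit_on_train = FALSE,
                            seed = 1L) {
  param_mode <- match.arg(param_mode)
  structure(list(frac_train = frac_train, threshold = threshold,
                 max_missing = max_missing, nnmf_rank = nnmf_rank,
                 nnmf_max_iter = nnmf_max_iter, eps_mi = eps_mi,
                 alpha_range = alpha_range, lasso_iel = lasso_iel,
                 deep_iel = deep_iel, width = as.integer(width),
                 depth = as.integer(depth), train = train,
                 param_mode = param_mode, pool_cap = pool_cap,
                 k_cap = as.integer(k_cap), cv_reps = as.integer(cv_reps),
                 shap_samples = as.integer(shap_samples),
                 shap_background_n = as.integer(shap_background_n),
                 shap_max_rows = as.integer(shap_max_rows),
                 fit_on_train = fit_on_train,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Reduced pipeline configuration for fast end-to-end runs
#'
#' Same stages as [pipeline_config()] with a reduced search and training
#' budget: population 16 (restart 8), short plateau windows, capped
#' generations and epochs, 64-unit hidden layers, repeated 8-fold
#' cross-validation, and a fine-selection pool capped at the 20
#' strongest-univariate LASSO selections. Sized so one full experiment runs
#' in about a minute on one CPU.
#'
#' @param seed master seed.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a `"pipeline_config"`.
#' @export
smoke_config <- function(seed = 1L, ...) {
  deep <- iel_config(pop_size = 16, n_recombine_parents = 6, n_mutate = 3,
                     n_new_random = 10,
                     restart_pop_size = 8, restart_recombine_parents = 4,
                     restart_mutate = 2, restart_new_random = 4,
                     plateau_window = 3, plateau_delta = 1e-3,
                     max_generations = 12, restart_max_generations = 5,
                     seed = seed)
  lasso <- iel_config(pop_size = 20, n_recombine_parents = 8, n_mutate = 4,
                      n_new_random = 12,
                      restart_pop_size = 10, restart_recombine_parents = 4,
                      restart_mutate = 2, restart_new_random = 6,
                      plateau_window = 6, plateau_delta = 1e-4,
                      max_generations = 30, seed = seed)
  pipeline_config(deep_iel = deep, lasso_iel = lasso, width = 64L,
                  train = train_config(max_epochs = 30),
                  nnmf_max_iter = 200, pool_cap = 20L, k_cap = 8L,
                  cv_reps = 2L,
                  shap_samples = 8L,
                  shap_background_n = 50L, shap_max_rows = 30L,
                  seed = seed, ...)
}

preprocess_sample <- function(sample, meta, config, seed) {
  pr_train <- preprocess_partition(sample$train$x, meta,
                                   max_missing = config$max_missing,
                                   nnmf_rank = config$nnmf_rank,
                                   nnmf_max_iter = config$nnmf_max_iter,
                                   seed = derive_seed("prep-train", seed))
  pr_test <- preprocess_partition(sample$test$x, meta,
                                  max_missing = config$max_missing,
                                  nnmf_rank = config$nnmf_rank,
                                  nnmf_max_iter = config$nnmf_max_iter,
                                  seed = derive_seed("prep-test", seed))
  list(train = pr_train, test = pr_test)
}

#' Run one experiment of the prediction pipeline
#'
#' Executes, in order: unrelated-participant selection, the 70/30 partition,
#' matched case-control sample construction for the requested subscale and
#' case mode, per-partition preprocessing, coarse feature selection (filter
#' + IEL-tuned LASSO) on the training partition, the joint IEL/deep-network
#' optimization with cross-validated BIC fitness, a final refit of the best
#' genome, held-out evaluation, and SHAP interpretation of the final model.
#' With `scope = "neural_only"` the candidate pool is restricted to
#' neural-tagged features before coarse selection.
#'
#' @param cohort an `"iel_cohort"`.
#' @param subscale target subscale (see [subscales()]).
#' @param mode `"new_onset"` or `"prevailing"`.
#' @param scope `"multimodal"` or `"neural_only"`.
#' @param config a [pipeline_config()].
#' @param seed seed overriding `config$seed` (optional).
#' @return object of class `"iel_experiment"` with the evaluation report,
#'   importance report, selection result, IEL fit, final genome/model, and
#'   stage bookkeeping.
#' @export
run_experiment <- function(cohort, subscale, mode = c("new_onset", "prevailing"),
                           scope = c("multimodal", "neural_only"),
                           config = smoke_config(), seed = NULL) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  seed <- as.integer(seed %||% config$seed)
  t0 <- proc.time()[["elapsed"]]

  target <- target_spec(subscale, config$threshold, mode)
  ids <- select_unrelated(cohort)
  partition <- partition_train_test(ids, config$frac_train,
                                    seed = derive_seed("partition", seed))

  meta <- cohort$feature_meta
  if (scope == "neural_only") {
    keep <- meta$feature[meta$modality == "neural"]
    cohort$features <- cohort$features[, keep, drop = FALSE]
    meta <- meta[meta$modality == "neural", , drop = FALSE]
    cohort$feature_meta <- meta
  }

  sample <- build_case_control_sample(cohort, target, partition)
  prep <- preprocess_sample(sample, meta, config, seed)
  x_train <- prep$train$x
  y_train <- unname(sample$train$y)

  ## coarse selection on the training partition
  filt <- filter_nonzero_relationship(x_train, y_train, prep$train$meta,
                                      eps_mi = config$eps_mi)
  retained <- filt$feature[filt$retained]
  if (length(retained) < 2)
    stopf("association filter retained %d features", length(retained))
  lasso_cfg <- config$lasso_iel
  if (!is.null(lasso_cfg)) lasso_cfg$seed <- derive_seed("lasso", seed)
  selection <- select_with_lasso_iel(x_train[, retained, drop = FALSE],
                                     y_train,
                                     alpha_range = config$alpha_range,
                                     config = lasso_cfg,
                                     seed = derive_seed("lasso", seed))
  pool <- selection$selected
  if (length(pool) > config$pool_cap) {
    ## rank by marginal (univariate) strength: LASSO coefficients split
    ## weight among correlated features, univariate slopes do not
    ord <- order(abs(selection$univariate), decreasing = TRUE)
    pool <- selection$selected[ord][seq_len(config$pool_cap)]
  }
  if (length(pool) == 0)
    stopf("coarse selection selected no features; widen alpha_range")
  if (length(pool) == 1) {
    ## the joint search needs at least two candidates; pad with the
    ## strongest remaining filtered feature by univariate association
    rest <- setdiff(retained, pool)
    slope <- vapply(rest, function(f) {
      v <- x_train[, f]
      abs(stats::cov(v, y_train) / max(stats::var(v), 1e-12))
    }, 0)
    pool <- c(pool, rest[which.max(slope)])
    warnf("coarse selection kept a single feature; padded pool with '%s'",
          pool[2])
  }

  ## joint hyperparameter + fine feature selection with deep-network fitness
  deep_cfg <- config$deep_iel
  deep_cfg$seed <- derive_seed("deep", seed)
  deep_cfg$feature_count_range[2] <-
    min(deep_cfg$feature_count_range[2], length(pool))
  ## common random numbers: one CV seed for every genome, so fitness
  ## differences reflect subsets/hyperparameters, not lucky fold draws
  cv_seed <- derive_seed("cv-fitness", seed)
  fitness <- function(genome) {
    cv_fitness(x_train, y_train, genome,
               width = config$width, depth = config$depth,
               config = config$train, param_mode = config$param_mode,
               k_cap = config$k_cap, n_rep = config$cv_reps, seed = cv_seed)
  }
  iel <- run_iel(fitness, feature_pool = pool, config = deep_cfg)

  final <- cv_fitness(x_train, y_train, iel$best_genome,
                      width = config$width, depth = config$depth,
                      config = config$train, param_mode = config$param_mode,
                      k_cap = config$k_cap, n_rep = config$cv_reps,
                      seed = cv_seed, refit = TRUE)
  model <- final$model

  ## held-out evaluation (test preprocessing refit independently by default)
  x_test <- if (config$fit_on_train) {
    ## reuse training statistics: re-apply training scaling to raw test rows
    align_features(apply_train_stats(sample$test$x, prep$train), colnames(x_train))
  } else {
    align_features(prep$test$x, colnames(x_train))
  }
  y_test <- unname(sample$test$y)
  evalrep <- test_metrics(model, x_test, y_test)

  ## SHAP on the held-out rows against a training background
  xe <- x_test[, model$features, drop = FALSE]
  if (nrow(xe) > config$shap_max_rows)
    xe <- xe[seq_len(config$shap_max_rows), , drop = FALSE]
  bg <- shap_background(x_train[, model$features, drop = FALSE],
                        n = config$shap_background_n,
                        seed = derive_seed("shap-bg", seed))
  importance <- shap_importances(model, xe, bg,
                                 n_samples = config$shap_samples,
                                 exact = length(model$features) <= 10,
                                 seed = derive_seed("shap", seed))

  structure(list(
    subscale = subscale, mode = mode, scope = scope, seed = seed,
    target = target,
    counts = c(candidates = ncol(cohort$features),
               preprocessed = ncol(x_train),
               filtered = length(retained),
               selected = length(pool),
               final = length(model$features)),
    selection = selection,
    iel = iel,
    genome = iel$best_genome,
    fitness = final[setdiff(names(final), "model")],
    model = model,
    eval = evalrep,
    roc = evalrep$roc,
    importance = importance,
    sample_sizes = c(train = length(y_train), test = length(y_test)),
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "iel_experiment")
}

## Re-apply training-partition statistics to raw test rows (fit-on-train
## toggle): training one-hot levels, trim bounds and min-max bounds from the
## preprocessing report; missing entries fall back to the training column
## mean (in place of refitting the factorization on test rows).
apply_train_stats <- function(x_raw, prep_train) {
  rep_f <- prep_train$report$features
  ref <- prep_train$x
  out <- matrix(0, nrow(x_raw), ncol(ref),
                dimnames = list(rownames(x_raw), colnames(ref)))
  get_stat <- function(nm, col) {
    v <- rep_f[[col]]
    if (is.null(v)) return(NA_real_)
    v[match(nm, rep_f$feature)]
  }
  for (j in seq_len(ncol(ref))) {
    nm <- colnames(ref)[j]
    fill <- mean(ref[, j])
    if (!nm %in% colnames(x_raw) && grepl("=", nm, fixed = TRUE)) {
      base <- sub("=[^=]*$", "", nm)
      lvl <- suppressWarnings(as.numeric(sub("^.*=", "", nm)))
      if (base %in% colnames(x_raw)) {
        v <- x_raw[, base]
        out[, j] <- ifelse(is.na(v), fill, as.numeric(v == lvl))
      } else {
        out[, j] <- fill
      }
    } else if (nm %in% colnames(x_raw)) {
      v <- x_raw[, nm]
      lo_t <- get_stat(nm, "lower"); hi_t <- get_stat(nm, "upper")
      if (is.finite(lo_t) && is.finite(hi_t)) v <- clip(v, lo_t, hi_t)
      lo <- get_stat(nm, "min"); hi <- get_stat(nm, "max")
      if (!is.finite(lo) || !is.finite(hi)) { lo <- 0; hi <- 1 }
      v <- (v - lo) / max(hi - lo, 1e-12)
      out[, j] <- ifelse(is.na(v), fill, clip(v, 0, 1))
    } else {
      out[, j] <- fill
    }
  }
  out
}

#' @export
print.iel_experiment <- function(x, ...) {
  cat(sprintf("Experiment: %s / %s / %s\n", x$subscale, x$mode, x$scope))
  cat(sprintf("  features: %d candidates -> %d preprocessed -> %d filtered -> %d selected -> %d final\n",
              x$counts[["candidates"]], x$counts[["preprocessed"]],
              x$counts[["filtered"]], x$counts[["selected"]],
              x$counts[["final"]]))
  cat(sprintf("  sample  : %d train / %d test rows (balanced)\n",
              x$sample_sizes[["train"]], x$sample_sizes[["test"]]))
  cat(sprintf("  test    : accuracy %.1f%%, precision %.1f%%, recall %.1f%%, AUROC %s\n",
              100 * x$eval$accuracy, 100 * x$eval$precision,
              100 * x$eval$recall,
              if (x$eval$auroc_defined) sprintf("%.3f", x$eval$auroc) else "NA"))
  cat(sprintf("  SHAP    : mean importance %.4f over %d final predictors\n",
              x$importance$mean_importance, x$counts[["final"]]))
  invisible(x)
}

#' @export
summary.iel_experiment <- function(object, ...) {
  data.frame(subscale = object$subscale, mode = object$mode,
             scope = object$scope,
             accuracy = 100 * object$eval$accuracy,
             precision = 100 * object$eval$precision,
             recall = 100 * object$eval$recall,
             auroc = object$eval$auroc,
             n_final = object$counts[["final"]],
             mean_importance = object$importance$mean_importance,
             stringsAsFactors = FALSE)
}

#' The 12-experiment grid
#'
#' @return data frame of descriptors: 3 subscales x {new_onset, prevailing}
#'   x {multimodal, neural_only}.
#' @export
experiment_grid <- function() {
  expand.grid(subscale = subscales(),
              mode = c("new_onset", "prevailing"),
              scope = c("multimodal", "neural_only"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run a grid of experiments and assemble the manifest
#'
#' Runs each descriptor with an independent seed derived from the master
#' seed; failures are recorded and do not abort the other experiments. The
#' accuracy-importance correlation is computed across completed experiments
#' (with a warning when some failed).
#'
#' @param cohort an `"iel_cohort"`.
#' @param config a [pipeline_config()].
#' @param grid descriptor data frame (default the full 12-experiment
#'   [experiment_grid()]).
#' @param seed master seed (default `config$seed`).
#' @return object of class `"iel_grid"`: `experiments` (list), `summary`
#'   (data frame), `correlation` (a `"correlation_result"` or `NULL`),
#'   `failures`.
#' @export
run_grid <- function(cohort, config = smoke_config(),
                     grid = experiment_grid(), seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  experiments <- vector("list", nrow(grid))
  failures <- character(0)
  for (i in seq_len(nrow(grid))) {
    tag <- paste(grid$subscale[i], grid$mode[i], grid$scope[i], sep = "/")
    res <- tryCatch(
      run_experiment(cohort, grid$subscale[i], grid$mode[i], grid$scope[i],
                     config = config,
                     seed = derive_seed(tag, seed)),
      error = function(e) {
        warnf("experiment %s failed: %s", tag, conditionMessage(e))
        structure(list(tag = tag, message = conditionMessage(e)),
                  class = "iel_experiment_failure")
      })
    experiments[[i]] <- res
    if (inherits(res, "iel_experiment_failure")) failures <- c(failures, tag)
  }
  ok <- !vapply(experiments, inherits, TRUE, "iel_experiment_failure")
  summary_df <- do.call(rbind, lapply(experiments[ok], summary))
  correlation <- NULL
  if (sum(ok) >= 3) {
    correlation <- accuracy_importance_correlation(summary_df)
    if (length(failures))
      warnf("correlation computed over %d completed experiments (%d failed)",
            sum(ok), length(failures))
  }
  structure(list(experiments = experiments, summary = summary_df,
                 correlation = correlation, failures = failures,
                 grid = grid, seed = seed),
            class = "iel_grid")
}

#' @export
print.iel_grid <- function(x, ...) {
  cat(sprintf("Experiment grid: %d planned, %d completed, %d failed\n",
              nrow(x$grid), nrow(x$summary) %||% 0, length(x$failures)))
  if (!is.null(x$summary)) {
    df <- x$summary
    df$accuracy <- round(df$accuracy, 1)
    df$precision <- round(df$precision, 1)
    df$recall <- round(df$recall, 1)
    df$auroc <- round(df$auroc, 3)
    df$mean_importance <- round(df$mean_importance, 4)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$correlation))
    cat(sprintf("Accuracy-importance correlation: r = %.3f, r^2 = %.3f\n",
                x$correlation$r, x$correlation$r_squared))
  invisible(x)
}

#' Write the report files for a completed grid
#'
#' Emits `metrics.csv` (Accuracy/Precision/Recall/AUROC per experiment),
#' one `predictors_<experiment>.csv` per completed experiment (ranked final
#' predictors with their group-level importances and a closing Mean row),
#' per-experiment ROC point files, and `correlation.csv` with the
#' accuracy-importance pairs and log-accuracy plotting values.
#'
#' @param manifest an `"iel_grid"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
emit_reports <- function(manifest, dir) {
  stopifnot(inherits(manifest, "iel_grid"))
  ok <- !vapply(manifest$experiments, inherits, TRUE, "iel_experiment_failure")
  if (!any(ok)) return(invisible(character(0)))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create '%s'", dir)
  files <- character(0)
  metrics <- manifest$summary
  names(metrics)[names(metrics) == "accuracy"] <- "Accuracy (%)"
  names(metrics)[names(metrics) == "precision"] <- "Precision (%)"
  names(metrics)[names(metrics) == "recall"] <- "Recall (%)"
  names(metrics)[names(metrics) == "auroc"] <- "AUROC"
  f <- file.path(dir, "metrics.csv")
  utils::write.csv(metrics, f, row.names = FALSE)
  files <- c(files, f)
  for (exp in manifest$experiments[ok]) {
    tag <- paste(exp$subscale, exp$mode, exp$scope, sep = "_")
    gi <- exp$importance$group_importance[exp$importance$ranking]
    tab <- data.frame(predictor = c(names(gi), "Mean"),
                      importance = c(unname(gi), mean(gi)),
                      stringsAsFactors = FALSE)
    f <- file.path(dir, paste0("predictors_", tag, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(exp$roc)) {
      f <- file.path(dir, paste0("roc_", tag, ".csv"))
      utils::write.csv(exp$roc$points, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if (!is.null(manifest$correlation)) {
    f <- file.path(dir, "correlation.csv")
    utils::write.csv(manifest$correlation$pairs, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
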