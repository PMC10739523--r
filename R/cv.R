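## Stratified k-fold fitness evaluation: k tied to model size, BIC assembled
## from the summed held-out log-likelihood.

#' Plan a stratified k-fold split with model-size-dependent k
#'
#' The number of splits is the nearest integer above `n / d` (sample size
#' over number of features in the model), clipped into
#' `[2, min(20, minority class count)]`; the upper cap keeps folds
#' non-degenerate when `d` is very small. Fold assignment is stratified by
#' label with a fixed seed.
#'
#' @param n sample size (must be >= 4).
#' @param d number of features in the model (>= 2).
#' @param y binary label vector of length `n` (for stratification).
#' @param k_cap upper cap on k (default 20).
#' @param seed integer seed.
#' @return list of class `"cv_plan"`: `k` and `folds` (integer vector in
#'   `1..k` per row; per-fold class proportions within one unit of overall).
#' @export
plan_cv <- function(n, d, y, k_cap = 20L, seed = 1L) {
  stopifnot(n >= 4, d >= 2, length(y) == n)
  minority <- min(table(y))
  if (minority < 2) stopf("minority class has fewer than 2 observations")
  k <- ceiling(n / d)
  k <- max(2L, min(k, k_cap, minority))
  set.seed(seed)
  folds <- integer(n)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(k = as.integer(k), folds = folds), class = "cv_plan")
}

#' Assemble a BIC from parameter count, sample size and log-likelihood
#'
#' `BIC = p * ln(n) - 2 * L`, the fitness used throughout the evolutionary
#' search (lower is better).
#'
#' @param p parameter count.
#' @param n number of observations.
#' @param loglik summed log-likelihood `L`.
#' @return the BIC value.
#' @export
bic_from_loglik <- function(p, n, loglik) p * log(n) - 2 * loglik

stratified_split <- function(y, frac, seed) {
  set.seed(seed)
  hold <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_hold <- max(1L, round((1 - frac) * length(idx)))
    n_hold <- min(n_hold, length(idx) - 1L)
    hold <- c(hold, sample(idx, n_hold))
  }
  hold
}

#' Cross-validated BIC fitness of one genome
#'
#' Trains one network per fold on the genome's feature subset with the
#' genome's learning hyperparameters; each fold's training rows are further
#' split 80/20 (stratified) for early stopping, so the held-out fold enters
#' only the fitness likelihood. The summed held-out log-likelihood over all
#' `n` rows, together with the parameter count, gives
#' `BIC = p * ln(n) - 2 * L`.
#'
#' The complexity term defaults to the full trainable parameter count of the
#' network; `param_mode = "n_features"` instead uses the input dimension,
#' which keeps the per-feature BIC cost commensurate with attainable
#' likelihood gains at case-control sample sizes (the pipeline's choice).
#'
#' @param x feature matrix (will be subset to `genome$subset` when present).
#' @param y binary labels.
#' @param genome an IEL genome (hyperparameters + feature subset).
#' @param width,depth hidden architecture (defaults 300/3).
#' @param config a [train_config()].
#' @param param_mode `"full"` or `"n_features"`.
#' @param k_cap cap on the number of folds.
#' @param n_rep number of repeated cross-validation rounds (distinct fold
#'   assignments) whose summed log-likelihoods are averaged; repetition
#'   damps fold-assignment luck in the fitness at small n.
#' @param seed integer seed; every stochastic step derives from it, so the
#'   record is deterministic per genome.
#' @param refit also refit a final model on all rows (inner split for early
#'   stopping only).
#' @return list of class `"fitness_record"`: `bic`, `log_likelihood`,
#'   `param_count`, `n_obs`, `cv` (per-fold detail of the last round),
#'   `genome`, and `model` (when `refit = TRUE`).
#' @export
cv_fitness <- function(x, y, genome, width = 300L, depth = 3L,
                       config = train_config(),
                       param_mode = c("full", "n_features"),
                       k_cap = 20L, n_rep = 1L, seed = 1L, refit = FALSE) {
  param_mode <- match.arg(param_mode)
  feats <- genome$subset
  if (!is.null(feats)) x <- x[, feats, drop = FALSE]
  n <- nrow(x)
  d <- ncol(x)
  rep_logliks <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    rseed <- derive_seed(paste0("rep", r), seed)
    plan <- plan_cv(n, d, y, k_cap = k_cap, seed = derive_seed("cvplan", rseed))
    loglik <- 0
    fold_detail <- data.frame(fold = seq_len(plan$k), n_val = NA_integer_,
                              val_loss = NA_real_, loglik = NA_real_)
    for (f in seq_len(plan$k)) {
      hold <- plan$folds == f
      x_tr <- x[!hold, , drop = FALSE]; y_tr <- y[!hold]
      inner <- stratified_split(y_tr, 0.8,
                                derive_seed(paste0("inner", f), rseed))
      model <- train_network(x_tr[-inner, , drop = FALSE], y_tr[-inner],
                             x_tr[inner, , drop = FALSE], y_tr[inner],
                             hyper = genome$hyper,
                             spec = network_spec(d, width, depth),
                             config = config,
                             seed = derive_seed(paste0("fold", f), rseed))
      p_hold <- mlp_forward(model$params, x[hold, , drop = FALSE])$probs
      p_true <- ifelse(y[hold] == 1L, p_hold[, 2], p_hold[, 1])
      ll <- sum(log(pmax(p_true, 1e-12)))
      loglik <- loglik + ll
      fold_detail$n_val[f] <- sum(hold)
      fold_detail$val_loss[f] <- -ll / sum(hold)
      fold_detail$loglik[f] <- ll
    }
    rep_logliks[r] <- loglik
  }
  loglik <- mean(rep_logliks)
  p <- if (param_mode == "full") mlp_param_count(d, width, depth) else d
  rec <- list(bic = bic_from_loglik(p, n, loglik),
              log_likelihood = loglik, param_count = p, n_obs = n,
              k = plan$k, cv = fold_detail, genome = genome)
  if (refit) {
    ## best of three restarts by inner-validation loss: one training run on
    ## a few dozen rows is high-variance, and this model is the one that
    ## faces the held-out test partition
    inner <- stratified_split(y, 0.8, derive_seed("refit-inner", seed))
    cands <- lapply(1:3, function(r)
      train_network(x[-inner, , drop = FALSE], y[-inner],
                    x[inner, , drop = FALSE], y[inner],
                    hyper = genome$hyper,
                    spec = network_spec(d, width, depth),
                    config = config,
                    seed = derive_seed(paste0("refit", r), seed)))
    rec$model <- cands[[which.min(vapply(cands, `[[`, 0, "val_loss"))]]
  }
  class(rec) <- "fitness_record"
  rec
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("Fitness: BIC %.4f = %s * ln(%d) - 2 * (%.4f)  [k = %d folds]\n",
              x$bic, format(x$param_count, big.mark = ","), x$n_obs,
              x$log_likelihood, x$k))
  invisible(x)
}
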