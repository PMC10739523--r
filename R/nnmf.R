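#' Impute missing entries by masked non-negative matrix factorization
#'
#' Fits a rank-`r` factorization `X ~ W H` by multiplicative updates that
#' minimize the squared reconstruction error over *observed* entries only
#' (the missing-entry cost is masked out rather than treated as zero), then
#' fills each missing entry with the corresponding `(WH)` value clipped to
#' `[0, 1]`. Observed entries are always preserved. Input values must lie in
#' `[0, 1]`, which the min-max scaling stage guarantees.
#'
#' With `rank = "auto"` the rank is chosen from `{2, 4, 8, 16}` by masking a
#' random 10% holdout of the observed entries and picking the rank with the
#' lowest holdout reconstruction RMSE.
#'
#' @param x numeric matrix in `[0, 1]` with `NA` for missing entries.
#' @param rank integer factorization rank, or `"auto"`.
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol relative change in observed-entry RMSE below which the fit is
#'   declared converged.
#' @param seed integer seed for the random initialization.
#' @return list with `x` (completed matrix), `W`, `H`, `rank`, `iterations`,
#'   `converged`, and `objective` (final observed RMSE). If `max_iter` is
#'   reached without convergence the best iterate is returned with a warning.
#' @export
nnmf_impute <- function(x, rank = 8, max_iter = 1000, tol = 1e-8, seed = 1L) {
  stopifnot(is.matrix(x))
  obs <- !is.na(x)
  if (any(x[obs] < 0 | x[obs] > 1))
    stopf("nnmf_impute expects values in [0,1]; run min-max scaling first")
  if (all(obs)) {
    return(list(x = x, W = NULL, H = NULL, rank = NA_integer_,
                iterations = 0L, converged = TRUE, objective = 0))
  }
  if (identical(rank, "auto")) {
    rank <- choose_nnmf_rank(x, candidates = c(2L, 4L, 8L, 16L),
                             max_iter = max_iter, tol = tol, seed = seed)
  }
  rank <- max(1L, min(as.integer(rank), nrow(x), ncol(x)))
  fit <- nnmf_fit(x, obs, rank, max_iter, tol, seed)
  filled <- x
  rec <- fit$W %*% fit$H
  filled[!obs] <- clip(rec[!obs], 0, 1)
  if (!fit$converged)
    warnf("NNMF did not converge in %d iterations (final RMSE %.3g); using best iterate",
          max_iter, fit$objective)
  list(x = filled, W = fit$W, H = fit$H, rank = rank,
       iterations = fit$iterations, converged = fit$converged,
       objective = fit$objective)
}

nnmf_fit <- function(x, obs, rank, max_iter, tol, seed) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  xm <- x
  xm[!obs] <- 0
  mobs <- 1 * obs
  mu <- mean(x[obs])
  W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank) * sqrt(mu / rank)
  H <- matrix(stats::runif(rank * p, 0.1, 1), rank, p) * sqrt(mu / rank)
  eps <- 1e-12
  prev <- Inf
  converged <- FALSE
  it <- 0L
  n_obs <- sum(obs)
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    W <- W * (xm %*% t(H)) / ((mobs * WH) %*% t(H) + eps)
    WH <- W %*% H
    H <- H * (t(W) %*% xm) / (t(W) %*% (mobs * WH) + eps)
    if (it %% 5 == 0 || it == max_iter) {
      WH <- W %*% H
      rmse <- sqrt(sum(((x - WH)[obs])^2) / n_obs)
      if (is.finite(prev) && abs(prev - rmse) <= tol * max(prev, 1e-12)) {
        converged <- TRUE
        prev <- rmse
        break
      }
      prev <- rmse
    }
  }
  list(W = W, H = H, iterations = it, converged = converged, objective = prev)
}

choose_nnmf_rank <- function(x, candidates, max_iter, tol, seed) {
  obs_idx <- which(!is.na(x))
  set.seed(derive_seed("nnmf-rank", seed))
  n_hold <- max(1L, floor(0.1 * length(obs_idx)))
  hold <- sample(obs_idx, n_hold)
  xh <- x
  xh[hold] <- NA
  best <- candidates[1]; best_err <- Inf
  for (r in candidates) {
    r <- min(r, nrow(x), ncol(x))
    fit <- nnmf_fit(xh, !is.na(xh), r, max_iter, tol, seed)
    rec <- fit$W %*% fit$H
    err <- sqrt(mean((rec[hold] - x[hold])^2))
    if (err < best_err) { best_err <- err; best <- r }
  }
  best
}
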