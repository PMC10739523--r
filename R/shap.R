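## Shapley additive explanations for tabular classifiers, model-agnostic:
## permutation sampling against a background set, with exact subset
## enumeration for small feature counts.

as_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "mlp_model")) return(function(x) predict_proba(model, x))
  stopf("model must be a function(x) -> probabilities or an mlp_model")
}

#' Pick a background set summarizing the training rows
#'
#' Up to `n` rows; larger training sets are summarized by k-medoids
#' (`cluster::pam`) so the background spans the data without inflating the
#' explanation cost.
#'
#' @param x training feature matrix.
#' @param n background size (default 100).
#' @param seed integer seed.
#' @return matrix of background rows.
#' @export
shap_background <- function(x, n = 100L, seed = 1L) {
  if (nrow(x) <= n) return(x)
  set.seed(seed)
  if (nrow(x) > 1000) x <- x[sample.int(nrow(x), 1000), , drop = FALSE]
  pm <- cluster::pam(x, k = n, pamonce = 5)
  x[pm$id.med, , drop = FALSE]
}

# Value function v(S) for one explained row: mean_b f(x_S, b_notS), evaluated
# for a batch of subsets at once (rows = subsets x background).
subset_values <- function(f, x_row, background, subsets) {
  d <- length(x_row)
  nb <- nrow(background)
  ns <- length(subsets)
  big <- background[rep(seq_len(nb), ns), , drop = FALSE]
  for (si in seq_len(ns)) {
    S <- subsets[[si]]
    if (length(S))
      big[(si - 1L) * nb + seq_len(nb), S] <-
        matrix(x_row[S], nb, length(S), byrow = TRUE)
  }
  vals <- f(big)
  rowsum(vals, rep(seq_len(ns), each = nb))[, 1] / nb
}

shap_exact_row <- function(f, x_row, background) {
  d <- length(x_row)
  if (d > 12) stopf("exact enumeration supported for <= 12 features")
  n_sub <- bitwShiftL(1L, d)
  masks <- 0:(n_sub - 1L)
  subsets <- lapply(masks, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) != 0))
  v <- subset_values(f, x_row, background, subsets)
  sizes <- vapply(subsets, length, 0L)
  phi <- numeric(d)
  # weight |S|!(d-|S|-1)!/d! for S not containing i
  lfac <- lfactorial(0:d)
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(masks, bit) == 0L)
    s <- sizes[without]
    w <- exp(lfac[s + 1L] + lfac[d - s] - lfac[d + 1L])
    phi[i] <- sum(w * (v[without + bit] - v[without]))
  }
  phi
}

shap_sampling_row <- function(f, x_row, background, n_samples, seed) {
  d <- length(x_row)
  set.seed(seed)
  phi <- numeric(d)
  for (s in seq_len(n_samples)) {
    perm <- sample.int(d)
    subsets <- vector("list", d + 1L)
    subsets[[1L]] <- integer(0)
    for (j in seq_len(d)) subsets[[j + 1L]] <- perm[seq_len(j)]
    v <- subset_values(f, x_row, background, subsets)
    phi[perm] <- phi[perm] + diff(v)
  }
  phi / n_samples
}

#' SHAP feature importances for a set of rows
#'
#' Model-agnostic Shapley attributions of the class-1 probability. The value
#' of a feature coalition is the model's mean output over the background set
#' with the coalition's features taken from the explained row. Attributions
#' are estimated by permutation sampling (each permutation's contributions
#' telescope, so additivity `base + sum(phi) = f(x)` holds exactly up to
#' floating point); with `exact = TRUE` (feature count <= 12) all `2^d`
#' coalitions are enumerated with the exact Shapley kernel weights.
#'
#' @param model an `"mlp_model"` or a function `f(x) -> numeric` scores.
#' @param x rows to explain (matrix; typically the held-out test partition).
#' @param background background rows (typically from [shap_background()] on
#'   the training partition).
#' @param n_samples permutations per explained row (sampling mode).
#' @param seed integer seed.
#' @param exact enumerate all coalitions instead of sampling.
#' @param tol additivity residual above which a warning is raised.
#' @return list of class `"importance_report"`: `phi` (rows x features
#'   attribution matrix), `base_value`, `group_importance` (mean |phi| per
#'   feature), `ranking`, `mean_importance`, `additivity_residual`.
#' @export
shap_importances <- function(model, x, background, n_samples = 32L,
                             seed = 1L, exact = FALSE, tol = 1e-2) {
  f <- as_predict_fun(model)
  stopifnot(is.matrix(x), is.matrix(background),
            identical(colnames(x), colnames(background)))
  d <- ncol(x)
  phi <- matrix(0, nrow(x), d, dimnames = list(rownames(x), colnames(x)))
  for (i in seq_len(nrow(x))) {
    phi[i, ] <- if (exact)
      shap_exact_row(f, x[i, ], background)
    else
      shap_sampling_row(f, x[i, ], background, n_samples,
                        seed = derive_seed(paste0("shap", i), seed))
  }
  base_value <- mean(f(background))
  fx <- f(x)
  resid <- max(abs(base_value + rowSums(phi) - fx))
  if (resid > tol)
    warnf("SHAP additivity residual %.3g exceeds tol %.3g; increase n_samples",
          resid, tol)
  group <- colMeans(abs(phi))
  ranking <- names(sort(group, decreasing = TRUE))
  structure(list(phi = phi, base_value = base_value,
                 group_importance = group, ranking = ranking,
                 mean_importance = mean(group),
                 additivity_residual = resid,
                 n_samples = if (exact) NA_integer_ else n_samples,
                 exact = exact),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("SHAP importance report: %d rows x %d predictors (%s)\n",
              nrow(x$phi), ncol(x$phi),
              if (x$exact) "exact enumeration"
              else sprintf("%d permutations/row", x$n_samples)))
  top <- utils::head(x$ranking, 10)
  df <- data.frame(predictor = top,
                   importance = round(x$group_importance[top], 4))
  print(df, row.names = FALSE)
  cat(sprintf("  Mean importance %.4f; additivity residual %.2g\n",
              x$mean_importance, x$additivity_residual))
  invisible(x)
}
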