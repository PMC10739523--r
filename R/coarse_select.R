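## Coarse feature selection: association filter, then BIC-tuned LASSO.

digamma_ <- function(x) digamma(x)

#' Mutual information between a continuous feature and a discrete target
#'
#' Nearest-neighbour estimator for the mutual information (in nats) between
#' a 1-D continuous variable and a discrete class label (Ross 2014): for each
#' point, the distance to its k-th nearest neighbour *within its own class*
#' defines a radius, and the number of points of any class inside that radius
#' enters a digamma average. Ties are broken by an infinitesimal deterministic
#' jitter so discretized inputs do not degenerate the neighbour counts.
#'
#' @param x numeric vector.
#' @param y class labels (any atomic type).
#' @param k neighbour order (default 3).
#' @return estimated mutual information in nats (clamped at 0).
#' @export
mi_continuous <- function(x, y, k = 3L) {
  ok <- is.finite(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || length(unique(y)) < 2) return(0)
  set.seed(derive_seed("mi-jitter", n))
  x <- x + stats::runif(n, -1, 1) * 1e-10 * max(stats::sd(x), 1e-12)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  classes <- unique(y)
  nx <- integer(n)   # same-class sample size per point
  mvec <- integer(n) # neighbours of any class within the class-kNN radius
  for (cl in classes) {
    idx <- which(y == cl)
    ncl <- length(idx)
    kk <- min(k, ncl - 1L)
    if (kk < 1L) { nx[idx] <- ncl; mvec[idx] <- 1L; next }
    xv <- x[idx]
    for (ii in seq_along(idx)) {
      d <- abs(xv - xv[ii])
      r <- sort(d, partial = kk + 1L)[kk + 1L]  # k-th neighbour (self excluded)
      i_global <- idx[ii]
      m <- sum(abs(x - x[i_global]) <= r) - 1L  # any-class points in radius
      mvec[i_global] <- max(m, 1L)
      nx[i_global] <- ncl
    }
  }
  kk_used <- pmin(k, nx - 1L)
  kk_used[kk_used < 1L] <- 1L
  mi <- digamma_(n) - mean(digamma_(nx)) + mean(digamma_(kk_used)) -
    mean(digamma_(mvec))
  max(mi, 0)
}

#' Mutual information between two discrete variables (plug-in, nats)
#' @param x,y atomic vectors of equal length.
#' @return plug-in mutual information estimate in nats.
#' @export
mi_discrete <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  tab <- table(x[ok], y[ok])
  if (any(dim(tab) < 2)) return(0)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

anova_f <- function(x, y) {
  ok <- is.finite(x)
  x <- x[ok]; y <- y[ok]
  groups <- split(x, y)
  if (length(groups) < 2) return(0)
  n <- length(x)
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1L
  dfw <- n - length(groups)
  if (dfw <= 0 || ssw <= 0) return(0)
  (ssb / dfb) / (ssw / dfw)
}

chisq_stat <- function(x, y) {
  ok <- !is.na(x)
  tab <- table(x[ok], y[ok])
  if (any(dim(tab) < 2)) return(0)
  suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
}

#' Filter features with a non-zero relationship with the target
#'
#' Computes a chi-square statistic for categorical features, an ANOVA F
#' statistic for continuous features, and a mutual information estimate for
#' all features, against a binary target. A feature is retained iff its MI
#' exceeds `eps_mi` *or* its type-appropriate statistic is positive; constant
#' features are always dropped. This is a deliberately permissive filter —
#' literal non-zeroness, not a significance test.
#'
#' @param x numeric feature matrix (categorical columns as level codes or
#'   one-hot indicators).
#' @param y binary target vector.
#' @param meta optional feature metadata (used for the type tags); columns
#'   default to continuous when absent.
#' @param eps_mi MI retention threshold (default 1e-6).
#' @param k MI nearest-neighbour order for continuous features.
#' @return data frame of class `"filter_stats"`: feature, test used,
#'   statistic, mi, retained flag.
#' @export
filter_nonzero_relationship <- function(x, y, meta = NULL, eps_mi = 1e-6,
                                        k = 3L) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(unique(y[!is.na(y)])) != 2) stopf("target must be binary")
  types <- if (is.null(meta)) rep("continuous", ncol(x)) else
    meta$type[match(colnames(x), meta$feature)]
  types[is.na(types)] <- "continuous"
  categorical <- types %in% c("nominal", "ordinal", "binary")
  res <- data.frame(feature = colnames(x),
                    test = ifelse(categorical, "chisq", "anova"),
                    statistic = NA_real_, mi = NA_real_,
                    retained = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    obs <- v[!is.na(v)]
    if (length(unique(obs)) < 2) {
      res$statistic[j] <- 0; res$mi[j] <- 0
      next
    }
    if (categorical[j]) {
      res$statistic[j] <- chisq_stat(v, y)
      res$mi[j] <- mi_discrete(v, y)
    } else {
      res$statistic[j] <- anova_f(v, y)
      res$mi[j] <- mi_continuous(v, y, k = k)
    }
    res$retained[j] <- (res$mi[j] > eps_mi) || (res$statistic[j] > 0)
  }
  class(res) <- c("filter_stats", class(res))
  res
}

#' Fit a linear LASSO at a fixed penalty and score it by BIC
#'
#' The 0/1 target is treated as a linear-regression response (the shrinkage
#' step is a linear LASSO, not a logistic one). The penalty `alpha` is on the
#' `(1/2n)||y - Xb||^2 + alpha*||b||_1` scale. The model is scored with the
#' Gaussian-RSS form of the BIC,
#' `p_nz * ln(n) + n * ln(RSS/n)`, where `p_nz` counts nonzero coefficients
#' (intercept excluded).
#'
#' @param x numeric feature matrix, scaled to `[0, 1]`.
#' @param y binary (0/1) target.
#' @param alpha penalty level (>= 0; 0 gives ordinary least squares).
#' @param tol,max_iter solver control.
#' @return list with `coefficients` (named, including `(Intercept)`),
#'   `selected` (names of nonzero features), `p_nz`, `rss`, and `bic`.
#' @export
fit_lasso <- function(x, y, alpha, tol = 1e-9, max_iter = 1e6) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || !is.finite(alpha))
    stopf("alpha must be a single finite non-negative number")
  n <- nrow(x)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        standardize = FALSE, intercept = TRUE,
                        thresh = tol, maxit = max_iter)
  co <- as.matrix(stats::coef(fit, s = alpha, exact = TRUE, x = x, y = y,
                              thresh = tol, maxit = max_iter))
  beta <- co[-1, 1]
  intercept <- co[1, 1]
  pred <- intercept + as.vector(x %*% beta)
  rss <- sum((y - pred)^2)
  p_nz <- sum(beta != 0)
  ## a (near-)saturated linear fit sends the Gaussian log-likelihood to
  ## infinity and makes the BIC meaningless; rule such fits out
  saturated <- p_nz >= n - 1L || rss < 1e-8 * n * stats::var(y)
  bic <- if (saturated) Inf
         else p_nz * log(n) + n * log(max(rss, 1e-12) / n)
  list(coefficients = stats::setNames(c(intercept, beta),
                                      c("(Intercept)", colnames(x))),
       selected = colnames(x)[beta != 0],
       p_nz = p_nz, rss = rss, bic = bic)
}

#' Coarse feature selection with an IEL-tuned LASSO
#'
#' Runs the evolutionary engine over the LASSO penalty (log-uniform on
#' `alpha_range`) with the LASSO BIC as fitness, then reports the features
#' with nonzero coefficients at the best penalty, together with their
#' univariate regression coefficients against the target.
#'
#' @param x filtered, `[0, 1]`-scaled feature matrix.
#' @param y binary target.
#' @param alpha_range penalty search range (default `[1e-4, 10]`, log scale).
#' @param config an [iel_config()]; defaults to a compact single-phase
#'   search.
#' @param seed integer seed.
#' @return list of class `"selection_result"`: `selected`, `alpha`, `bic`,
#'   `coefficients` (LASSO), `univariate` (per-selected-feature slope),
#'   `counts` (input/filtered/selected bookkeeping), and the `iel` fit.
#' @export
select_with_lasso_iel <- function(x, y, alpha_range = c(1e-4, 10),
                                  config = NULL, seed = 1L) {
  if (is.null(config))
    config <- iel_config(pop_size = 30, n_recombine_parents = 12,
                         n_mutate = 6, n_new_random = 18,
                         plateau_window = 8, max_generations = 60,
                         seed = seed)
  ranges <- list(hyper_range("alpha", alpha_range[1], alpha_range[2],
                             shift = 0.05, log = TRUE))
  fitness <- function(genome) {
    fit <- fit_lasso(x, y, genome$hyper[["alpha"]])
    list(bic = fit$bic, fit = fit)
  }
  run <- run_iel(fitness, feature_pool = NULL, config = config,
                 ranges = ranges)
  best_alpha <- run$best_genome$hyper[["alpha"]]
  fit <- fit_lasso(x, y, best_alpha)
  if (length(fit$selected) == 0)
    stopf(paste("LASSO selected no features at alpha = %.4g;",
                "consider widening alpha_range"), best_alpha)
  uni <- vapply(fit$selected, function(f) {
    v <- x[, f]
    stats::cov(v, y) / max(stats::var(v), 1e-12)
  }, 0)
  structure(list(selected = fit$selected, alpha = best_alpha, bic = fit$bic,
                 coefficients = fit$coefficients[fit$selected],
                 univariate = uni,
                 counts = c(input = ncol(x), selected = length(fit$selected)),
                 iel = run),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("LASSO coarse selection: alpha = %.5g, BIC = %.3f\n",
              x$alpha, x$bic))
  cat(sprintf("  %d of %d features selected\n",
              x$counts[["selected"]], x$counts[["input"]]))
  invisible(x)
}
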