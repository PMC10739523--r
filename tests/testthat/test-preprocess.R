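mk_ft <- function(x, types = NULL, modality = "psychosocial") {
  if (is.null(types)) types <- rep("continuous", ncol(x))
  meta <- data.frame(feature = colnames(x),
                     modality = modality,
                     type = types,
                     n_levels = NA_integer_, stringsAsFactors = FALSE)
  feature_table(x, meta)
}

test_that("missingness filter drops strictly above 35% and keeps the boundary", {
  x <- cbind(a = c(rep(NA, 36), rnorm(64)),   # 36% missing -> dropped
             b = c(rep(NA, 35), rnorm(65)),   # exactly 35% -> kept
             c = rnorm(100))                  # complete -> kept
  ft <- drop_high_missing(mk_ft(x))
  expect_setequal(colnames(ft$x), c("b", "c"))
  expect_identical(ft$log$missingness$dropped, c(TRUE, FALSE, FALSE))
  # no missing -> identity
  ft2 <- drop_high_missing(mk_ft(x[, "c", drop = FALSE]))
  expect_identical(ft2$x[, "c"], x[, "c"])
})

test_that("one-hot encoding expands nominal and ordinal features", {
  x <- cbind(nom = c(1, 2, 3, 1, 2, NA), ord = c(1, 1, 2, 3, 3, 2),
             cont = rnorm(6))
  ft <- encode_one_hot(mk_ft(x, types = c("nominal", "ordinal", "continuous")))
  expect_setequal(colnames(ft$x),
                  c("nom=1", "nom=2", "nom=3", "ord=1", "ord=2", "ord=3",
                    "cont"))
  complete <- !is.na(x[, "nom"])
  expect_true(all(rowSums(ft$x[complete, c("nom=1", "nom=2", "nom=3")]) == 1))
  # a missing source value propagates to all derived columns
  expect_true(all(is.na(ft$x[6, c("nom=1", "nom=2", "nom=3")])))
  # ordinal variables are one-hot too, not integer-coded
  expect_true(all(ft$x[, "ord=2"] %in% c(0, 1)))
  # continuous column untouched
  expect_identical(ft$x[, "cont"], x[, "cont"])
  # too many levels looks like an id column
  xid <- cbind(id = seq_len(60))
  expect_error(encode_one_hot(mk_ft(xid, "nominal")), "id column")
})

test_that("outlier trimming clips to mean +/- 3 SD and spares constants", {
  set.seed(1)
  v <- c(rnorm(99), 10)
  x <- cbind(a = v, k = rep(1, 100))
  ft <- trim_outliers(mk_ft(x))
  mu <- mean(v); s <- sd(v)
  expect_equal(max(ft$x[, "a"]), min(max(v), mu + 3 * s))
  expect_true(all(ft$x[, "a"] >= mu - 3 * s & ft$x[, "a"] <= mu + 3 * s))
  expect_identical(ft$x[, "k"], x[, "k"])
  expect_true(ft$log$trim$constant[2])
  # all values inside the bounds -> identity
  ft2 <- trim_outliers(mk_ft(cbind(b = seq(-1, 1, length.out = 50))))
  expect_equal(ft2$x[, "b"], seq(-1, 1, length.out = 50))
})

test_that("min-max scaling maps to [0,1] with constants at 0", {
  x <- cbind(a = c(2, 4, 6), b = c(0, 1, 0), k = c(5, 5, 5))
  ft <- scale_minmax(mk_ft(x))
  expect_equal(unname(ft$x[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(ft$x[, "b"]), c(0, 1, 0))  # binary columns unchanged
  expect_equal(unname(ft$x[, "k"]), c(0, 0, 0))
})

test_that("rank-1 masked completion recovers the missing entry", {
  m <- matrix(c(1, 2, 2, 4) / 4, 2, 2, byrow = TRUE)
  m[2, 2] <- NA
  fit <- nnmf_impute(m, rank = 1, max_iter = 5000, tol = 1e-12)
  expect_lt(abs(fit$x[2, 2] - 1.0), 1e-3)
  expect_identical(fit$x[1, ], m[1, ])  # observed entries preserved
})

test_that("complete input is returned unchanged by the imputer", {
  m <- matrix(runif(20), 4, 5)
  expect_identical(nnmf_impute(m)$x, m)
})

test_that("NNMF imputation beats column-mean imputation on low-rank data", {
  set.seed(11)
  wins <- 0L
  for (rep in 1:20) {
    W <- matrix(runif(30 * 3), 30, 3)
    H <- matrix(runif(3 * 12), 3, 12)
    full <- W %*% H / max(W %*% H)
    x <- full
    mask <- matrix(runif(length(x)) < 0.2, nrow(x))
    x[mask] <- NA
    # guard: keep at least one observed entry per row/col
    x[1, ] <- full[1, ]; x[, 1] <- full[, 1]
    mask <- is.na(x)
    imp <- nnmf_impute(x, rank = 3, max_iter = 2000, tol = 1e-10,
                       seed = rep)$x
    colmean <- x
    for (j in seq_len(ncol(x)))
      colmean[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    rmse_nnmf <- sqrt(mean((imp[mask] - full[mask])^2))
    rmse_mean <- sqrt(mean((colmean[mask] - full[mask])^2))
    wins <- wins + (rmse_nnmf < rmse_mean)
  }
  expect_gte(wins, 18)
})

test_that("feature agglomeration merges clustered features by group", {
  set.seed(2)
  base1 <- rnorm(40); base2 <- rnorm(40)
  x <- cbind(g1a = base1, g1b = base1,             # identical pair
             g2a = base2, g2b = base2 + rnorm(40, 0, 0.01),
             solo = rnorm(40))
  ft <- mk_ft(x)
  # two identical features, one cluster -> the common column
  f1 <- agglomerate_features(ft, groups = list(G = c("g1a", "g1b")),
                             n_clusters = 1)
  expect_equal(unname(f1$x[, "G.1"]), base1)
  # n_clusters = group size -> identity up to renaming
  f2 <- agglomerate_features(ft, groups = list(G = c("g1a", "g2a")),
                             n_clusters = 2)
  expect_setequal(sort(c(f2$x[, "G.1"], f2$x[, "G.2"])),
                  sort(c(base1, base2)))
  # two orthogonal pairs, 2 clusters -> clusters recover the pairs
  f3 <- agglomerate_features(ft,
                             groups = list(G = c("g1a", "g1b", "g2a", "g2b")),
                             n_clusters = 2)
  map <- f3$log$agglomeration
  cl <- split(map$feature, map$cluster)
  expect_setequal(lapply(cl, sort),
                  list(c("g1a", "g1b"), c("g2a", "g2b")))
})

test_that("the composed stack yields a complete [0,1] matrix and spares neural features", {
  g <- small_cohort()
  co <- g$cohort
  idx <- seq_len(120)
  pr <- preprocess_partition(co$features[idx, ], co$feature_meta,
                             nnmf_max_iter = 300, seed = 9)
  expect_false(anyNA(pr$x))
  expect_true(all(pr$x >= 0 & pr$x <= 1))
  # neural features bypass everything except scaling: same ranking preserved
  nr <- co$feature_meta$feature[co$feature_meta$modality == "neural"][1]
  expect_equal(order(pr$x[, nr]), order(co$features[idx, nr]))
  # report covers trim/scale/impute accounting
  expect_s3_class(pr$report, "preprocess_report")
  expect_true(all(c("feature", "min", "max") %in% names(pr$report$features)))
})

test_that("partition statistics are fitted independently", {
  g <- small_cohort()
  co <- g$cohort
  a <- preprocess_partition(co$features[1:100, ], co$feature_meta,
                            nnmf_max_iter = 100, seed = 1)
  b <- preprocess_partition(co$features[101:200, ], co$feature_meta,
                            nnmf_max_iter = 100, seed = 1)
  nr <- grep("^nr", intersect(colnames(a$x), colnames(b$x)), value = TRUE)
  f <- nr[1]  # continuous neural feature: scaling bounds must differ
  ra <- a$report$features; rb <- b$report$features
  expect_false(isTRUE(all.equal(ra$min[match(f, ra$feature)],
                                rb$min[match(f, rb$feature)])))
})
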