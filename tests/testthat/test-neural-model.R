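test_that("parameter count formula matches an explicit weight census", {
  expect_equal(mlp_param_count(10), 184502)
  # census of an actually built network
  spec <- network_spec(7, width = 20, depth = 3)
  set.seed(1)
  params <- ielnet:::mlp_init(spec)
  census <- sum(vapply(params$W, length, 0L)) +
    sum(vapply(params$b, length, 0L))
  expect_equal(census, mlp_param_count(7, width = 20, depth = 3))
})

test_that("k follows the ceiling rule with caps and stratification", {
  y200 <- rep(0:1, each = 100)
  expect_identical(plan_cv(200, 10, y200)$k, 20L)
  y100 <- rep(0:1, each = 50)
  expect_identical(plan_cv(100, 7, y100)$k, 15L)
  y60 <- rep(0:1, each = 30)
  expect_identical(plan_cv(60, 50, y60)$k, 2L)
  # cap at the minority class count
  y_skew <- c(rep(0L, 96), rep(1L, 4))
  expect_identical(plan_cv(100, 2, y_skew)$k, 4L)
  expect_error(plan_cv(10, 2, c(rep(0L, 9), 1L)), "minority")
  # stratified: per-fold class counts within 1 of proportionality
  pl <- plan_cv(200, 10, y200, seed = 3)
  tab <- table(pl$folds, y200)
  expect_true(all(abs(tab - 5) <= 1))
  # folds partition the sample
  expect_identical(sort(unique(pl$folds)), 1:20)
})

test_that("BIC assembles exactly from its closed form", {
  expect_equal(bic_from_loglik(1000, 100, -50), 1000 * log(100) + 100,
               tolerance = 1e-12)
  expect_equal(round(bic_from_loglik(1000, 100, -50), 2), 4705.17)
})

test_that("the network solves a separable toy problem", {
  set.seed(6)
  n <- 120
  x <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- as.integer(x[, 1] > x[, 2])
  tr <- 1:90; va <- 91:120
  m <- train_network(x[tr, ], y[tr], x[va, ], y[va],
                     hyper = c(learning_rate = 0.005, beta1 = 0.9,
                               beta2 = 0.99),
                     spec = network_spec(2, width = 50, depth = 3),
                     config = train_config(max_epochs = 60), seed = 8)
  expect_equal(mean(classify(predict_proba(m, x[va, ])) == y[va]), 1.0)
})

test_that("shuffled labels bottom out near the entropy floor", {
  set.seed(9)
  n <- 160
  x <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(rep(0:1, each = n / 2))  # no learnable signal
  tr <- 1:120; va <- 121:160
  m <- train_network(x[tr, ], y[tr], x[va, ], y[va],
                     hyper = c(learning_rate = 0.002, beta1 = 0.9,
                               beta2 = 0.99),
                     spec = network_spec(4, width = 50, depth = 3),
                     config = train_config(max_epochs = 40), seed = 2)
  expect_gte(m$val_loss, log(2) - 0.05)
})

test_that("training and fitness are deterministic under fixed seeds", {
  set.seed(3)
  n <- 60
  x <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(0:1, each = 30)
  hy <- c(learning_rate = 0.004, beta1 = 0.92, beta2 = 0.98)
  args <- list(x[1:40, ], y[1:40], x[41:60, ], y[41:60], hyper = hy,
               spec = network_spec(3, width = 30, depth = 3), seed = 5)
  m1 <- do.call(train_network, args)
  m2 <- do.call(train_network, args)
  expect_identical(m1$val_loss, m2$val_loss)
  expect_identical(m1$params, m2$params)
  gen <- structure(list(hyper = hy, subset = paste0("f", 1:3),
                        lineage = "random"), class = "iel_genome")
  f1 <- cv_fitness(x, y, gen, width = 30, depth = 3,
                   config = train_config(max_epochs = 20), seed = 11)
  f2 <- cv_fitness(x, y, gen, width = 30, depth = 3,
                   config = train_config(max_epochs = 20), seed = 11)
  expect_identical(f1$bic, f2$bic)
  # BIC recomputable from the stored fields
  expect_identical(f1$bic, bic_from_loglik(f1$param_count, f1$n_obs,
                                           f1$log_likelihood))
  expect_equal(f1$log_likelihood, sum(f1$cv$loglik))
  # param_mode toggles the complexity term
  f3 <- cv_fitness(x, y, gen, width = 30, depth = 3,
                   config = train_config(max_epochs = 20),
                   param_mode = "n_features", seed = 11)
  expect_identical(f3$param_count, 3L)
})

test_that("probabilities are proper and the 0.5 boundary maps to class 1", {
  set.seed(4)
  x <- matrix(runif(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(x[, 1] > 0.5)
  m <- train_network(x[1:30, ], y[1:30], x[31:40, ], y[31:40],
                     hyper = c(learning_rate = 0.005, beta1 = 0.9,
                               beta2 = 0.99),
                     spec = network_spec(2, width = 20, depth = 2),
                     config = train_config(max_epochs = 20), seed = 1)
  fw <- ielnet:::mlp_forward(m$params, x)
  expect_equal(rowSums(fw$probs), rep(1, 40))
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  expect_identical(classify(c(0.5, 0.49999, 0.51)), c(1L, 0L, 1L))
  expect_error(predict_proba(m, x[, "a", drop = FALSE]), "lacks")
})
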