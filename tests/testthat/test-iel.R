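toy_ranges <- function() list(hyper_range("lr", 0, 1, shift = 0.01))

test_that("hyperparameter defaults match the documented tuning table", {
  r <- default_hyper_ranges()
  expect_identical(vapply(r, `[[`, "", "name"),
                   c("learning_rate", "beta1", "beta2"))
  expect_equal(r[[1]][c("low", "high", "shift")],
               list(low = 1e-5, high = 0.01, shift = 1e-4))
  expect_equal(r[[2]][c("low", "high", "shift")],
               list(low = 0.9, high = 0.999, shift = 1e-3))
  expect_equal(r[[3]][c("low", "high", "shift")],
               list(low = 0.9, high = 0.999, shift = 1e-3))
})

test_that("config size identities are enforced", {
  expect_silent(iel_config())
  expect_error(iel_config(pop_size = 90), "identity")
  expect_error(iel_config(restart_new_random = 5), "restart")
})

test_that("initial population respects ranges and subset bounds", {
  cfg <- iel_config(seed = 1)
  pool <- sprintf("f%03d", 1:120)
  set.seed(1)
  pop <- init_population(cfg, pool, default_hyper_ranges())
  expect_length(pop, 100)
  for (g in pop) {
    expect_between(g$hyper[["learning_rate"]], 1e-5, 0.01)
    expect_between(g$hyper[["beta1"]], 0.9, 0.999)
    expect_between(g$hyper[["beta2"]], 0.9, 0.999)
    expect_between(length(g$subset), 2, 50)
    expect_false(anyDuplicated(g$subset) > 0)
  }
  set.seed(1)
  pop2 <- init_population(cfg, pool, default_hyper_ranges())
  expect_identical(pop, pop2)
  expect_error(init_population(cfg, "one", default_hyper_ranges()), "at least 2")
})

test_that("recombination averages hyperparameters and pivots subsets", {
  cfg <- iel_config()
  rng <- default_hyper_ranges()
  a <- structure(list(hyper = c(learning_rate = 0.001, beta1 = 0.93,
                                beta2 = 0.95),
                      subset = c("1", "2", "3", "4"), lineage = "random"),
                 class = "iel_genome")
  b <- a; b$hyper[["learning_rate"]] <- 0.003
  b$subset <- c("5", "6", "7", "8")
  set.seed(1)
  child <- recombine(a, b, rng, pool = as.character(1:9), config = cfg)
  expect_equal(child$hyper[["learning_rate"]], 0.002)
  expect_identical(child$subset, c("1", "2", "7", "8"))
  expect_identical(child$lineage, "recombined")
  # identical parents -> child is the parent
  same <- recombine(a, a, rng, pool = as.character(1:9), config = cfg)
  expect_equal(same$hyper, a$hyper)
  expect_setequal(same$subset, a$subset)
})

test_that("mutation shifts one hyperparameter by its shift and clips", {
  cfg <- iel_config(feature_mutation_prob = 0)
  rng <- list(hyper_range("learning_rate", 1e-5, 0.01, shift = 1e-4))
  g <- structure(list(hyper = c(learning_rate = 0.005), subset = NULL,
                      lineage = "random"), class = "iel_genome")
  set.seed(2)
  deltas <- replicate(40, abs(mutate(g, rng, config = cfg)$hyper - 0.005))
  expect_true(all(abs(deltas - 1e-4) < 1e-12))
  # clipping at the range edge
  g$hyper[["learning_rate"]] <- 0.00999
  ups <- replicate(40, mutate(g, rng, config = cfg)$hyper)
  expect_true(all(ups <= 0.01))
  expect_true(any(ups == 0.01))
  g$hyper[["learning_rate"]] <- 0.95
  rngb <- list(hyper_range("learning_rate", 0.9, 0.999, shift = 1e-3))
  down <- min(replicate(20, mutate(g, rngb, config = cfg)$hyper))
  expect_equal(down, 0.949)
})

test_that("breeding conserves population size and child counts", {
  cfg <- iel_config(seed = 3)
  rng <- default_hyper_ranges()
  pool <- sprintf("f%02d", 1:60)
  set.seed(3)
  pop <- init_population(cfg, pool, rng)
  bic <- seq_along(pop)  # already sorted
  nxt <- breed_next_generation(pop, bic, cfg, pool, rng, phase = 1)
  expect_length(nxt, 100)
  lineage <- vapply(nxt, `[[`, "", "lineage")
  expect_identical(as.integer(table(lineage)[c("recombined", "mutated", "random")]),
                   c(20L, 20L, 60L))
  # restart-phase sizes
  pop2 <- init_population(cfg, pool, rng, n = 50)
  nxt2 <- breed_next_generation(pop2, seq_len(50), cfg, pool, rng, phase = 2)
  expect_length(nxt2, 50)
  lineage2 <- vapply(nxt2, `[[`, "", "lineage")
  expect_identical(as.integer(table(lineage2)[c("recombined", "mutated", "random")]),
                   c(10L, 10L, 30L))
})

test_that("plateau detection follows the trailing-window rule", {
  expect_false(detect_plateau(c(100, 90, 81, 72.9), window = 2, delta = 1e-3))
  expect_true(detect_plateau(rep(5, 11), window = 10, delta = 1e-3))
  h <- c(100, 99, 98.995)
  expect_false(detect_plateau(h[1:2], window = 2, delta = 1e-3))
  expect_true(detect_plateau(h, window = 2, delta = 1e-3))
})

test_that("restart importance is a weighted elite membership in [0,1]", {
  pool <- c("a", "b", "c", "d")
  mk <- function(s) structure(list(hyper = c(lr = 0.1), subset = s,
                                   lineage = "random"), class = "iel_genome")
  pop <- list(mk(c("a", "b")), mk(c("a", "c")), mk(c("a", "b")))
  imp <- feature_importance_for_restart(pop, bic = c(1, 1, 1), n_elite = 3,
                                        pool = pool)
  expect_equal(unname(imp["a"]), 1)        # in every elite genome
  expect_equal(unname(imp["d"]), 0)        # in none
  expect_equal(unname(imp["b"]), 2 / 3, tolerance = 1e-12)
  # identical membership patterns score identically
  pop2 <- list(mk(c("a", "b")), mk(c("a", "b")))
  imp2 <- feature_importance_for_restart(pop2, c(2, 5), n_elite = 2,
                                         pool = pool)
  expect_equal(unname(imp2["a"]), unname(imp2["b"]))
})

test_that("elbow finding matches brute-force distance computation", {
  pts <- data.frame(n_features = c(2, 10, 20, 50),
                    bic = c(100, 60, 58, 57))
  expect_equal(find_elbow(pts), 10)
  # brute-force check on normalized coordinates
  nf <- (pts$n_features - 2) / 48
  bb <- (pts$bic - 57) / 43
  d <- abs((bb[4] - bb[1]) * nf - (nf[4] - nf[1]) * bb +
             nf[4] * bb[1] - bb[4] * nf[1]) /
    sqrt((nf[4] - nf[1])^2 + (bb[4] - bb[1])^2)
  expect_equal(pts$n_features[which.max(d)], 10)
  # straight line -> smallest n at best bic
  line <- data.frame(n_features = c(2, 4, 6), bic = c(30, 20, 10))
  expect_equal(find_elbow(line), 6)
  flat <- data.frame(n_features = c(2, 4, 6), bic = c(10, 10, 10))
  expect_equal(find_elbow(flat), 2)
  # invariant to axis scaling
  pts2 <- pts; pts2$bic <- pts2$bic * 1000
  expect_equal(find_elbow(pts2), find_elbow(pts))
})

test_that("run_iel finds a closed-form optimum within mutation resolution", {
  cfg <- iel_config(pop_size = 30, n_recombine_parents = 12, n_mutate = 6,
                    n_new_random = 18, plateau_window = 6,
                    max_generations = 60, seed = 10)
  ranges <- list(hyper_range("lr", 0, 1, shift = 0.005))
  target <- 0.6180339
  fitness <- function(g) list(bic = (g$hyper[["lr"]] - target)^2)
  fit <- run_iel(fitness, feature_pool = NULL, config = cfg, ranges = ranges)
  expect_lt(abs(fit$best_genome$hyper[["lr"]] - target), 2 * 0.005)
})

test_that("a full run is reproducible and conserves model bookkeeping", {
  cfg <- iel_config(pop_size = 20, n_recombine_parents = 8, n_mutate = 4,
                    n_new_random = 12, restart_pop_size = 10,
                    restart_recombine_parents = 4, restart_mutate = 2,
                    restart_new_random = 6, plateau_window = 4,
                    max_generations = 15, restart_max_generations = 8,
                    seed = 77)
  pool <- sprintf("f%02d", 1:30)
  good <- pool[1:4]
  fitness <- function(g) {
    hit <- sum(good %in% g$subset)
    list(bic = 100 - 20 * hit + length(g$subset) +
           50 * (g$hyper[["learning_rate"]] - 0.005)^2)
  }
  a <- suppressWarnings(run_iel(fitness, pool, cfg))
  b <- suppressWarnings(run_iel(fitness, pool, cfg))
  expect_identical(a$best_genome, b$best_genome)
  expect_identical(a$best_bic, b$best_bic)
  # total models evaluated = sum of generation sizes
  expect_identical(a$n_models,
                   sum(vapply(a$history, `[[`, 0L, "pop_size")))
  # best-ever BIC is non-increasing
  trace <- vapply(a$history, `[[`, 0, "best_bic")
  expect_true(all(diff(trace) <= 0))
  # every evaluated genome satisfies the invariants
  for (h in a$history)
    for (g in h$population) {
      expect_between(length(g$subset), 2, 50)
      expect_between(g$hyper[["learning_rate"]], 1e-5, 0.01)
    }
})
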