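## Integrated Evolutionary Learning: population-based joint optimization of
## learning hyperparameters and feature subsets against a BIC fitness, with
## a recursive warm restart constrained to high-importance features.

#' Define a tunable hyperparameter range
#'
#' @param name hyperparameter name.
#' @param low,high bounds (`low < high`).
#' @param shift mutation shift; applied on the log10 scale when `log = TRUE`.
#' @param log sample and recombine on the log10 scale (geometric averaging).
#' @return list of class `"hyper_range"`.
#' @export
hyper_range <- function(name, low, high, shift, log = FALSE) {
  if (!is.numeric(low) || !is.numeric(high) || low >= high)
    stopf("hyper_range '%s': need low < high", name)
  if (!is.numeric(shift) || shift <= 0)
    stopf("hyper_range '%s': shift must be > 0", name)
  if (log && low <= 0) stopf("hyper_range '%s': log scale needs low > 0", name)
  structure(list(name = name, low = low, high = high, shift = shift,
                 log = log), class = "hyper_range")
}

#' Default learning-hyperparameter ranges for the deep network
#'
#' Learning rate in `[1e-5, 0.01]` with mutation shift `1e-4`; the Adam
#' moment decays beta1 and beta2 each in `[0.9, 0.999]` with shift `1e-3`.
#'
#' @return list of three [hyper_range()]s.
#' @export
default_hyper_ranges <- function() {
  list(hyper_range("learning_rate", 1e-5, 0.01, shift = 1e-4),
       hyper_range("beta1", 0.9, 0.999, shift = 1e-3),
       hyper_range("beta2", 0.9, 0.999, shift = 1e-3))
}

#' Configure the evolutionary engine
#'
#' Per generation, the population of `pop_size` models is ranked by BIC
#' (lower is better); the best `n_recombine_parents` are paired without
#' replacement into `n_recombine_parents/2` recombined children, the next
#' `n_mutate` are mutated into `n_mutate` children, and `n_new_random` fresh
#' random models complete the next generation. After the warm restart the
#' reduced sizes apply. Sizes must satisfy
#' `n_recombine_parents/2 + n_mutate + n_new_random = pop_size` (and the
#' restart analogue). The search stops when the best BIC fails to improve by
#' a relative `plateau_delta` over the trailing `plateau_window` generations,
#' or at `max_generations`.
#'
#' @param pop_size,n_recombine_parents,n_mutate,n_new_random phase-1 sizes
#'   (defaults 100/40/20/60).
#' @param restart_pop_size,restart_recombine_parents,restart_mutate,restart_new_random
#'   phase-2 sizes (defaults 50/20/10/30).
#' @param plateau_window,plateau_delta stopping rule (defaults 10, 1e-3).
#' @param feature_count_range genome subset size bounds (default `[2, 50]`).
#' @param feature_mutation_prob probability a mutation also swaps one feature.
#' @param max_generations,restart_max_generations hard caps per phase.
#' @param seed integer seed for the whole run.
#' @return list of class `"iel_config"`.
#' @export
iel_config <- function(pop_size = 100, n_recombine_parents = 40,
                       n_mutate = 20, n_new_random = 60,
                       restart_pop_size = 50, restart_recombine_parents = 20,
                       restart_mutate = 10, restart_new_random = 30,
                       plateau_window = 10, plateau_delta = 1e-3,
                       feature_count_range = c(2L, 50L),
                       feature_mutation_prob = 0.5,
                       max_generations = 400,
                       restart_max_generations = 200,
                       seed = 1L) {
  if (n_recombine_parents %% 2 != 0)
    stopf("n_recombine_parents must be even")
  if (n_recombine_parents / 2 + n_mutate + n_new_random != pop_size)
    stopf("size identity violated: recombine/2 + mutate + random must equal pop_size")
  if (restart_recombine_parents / 2 + restart_mutate + restart_new_random !=
      restart_pop_size)
    stopf("restart size identity violated")
  if (feature_count_range[1] < 2 || feature_count_range[2] < feature_count_range[1])
    stopf("feature_count_range must be [lo, hi] with lo >= 2")
  structure(list(
    pop_size = pop_size, n_elite = n_recombine_parents + n_mutate,
    n_recombine_parents = n_recombine_parents, n_mutate = n_mutate,
    n_new_random = n_new_random,
    restart_pop_size = restart_pop_size,
    restart_n_elite = restart_recombine_parents + restart_mutate,
    restart_recombine_parents = restart_recombine_parents,
    restart_mutate = restart_mutate, restart_new_random = restart_new_random,
    plateau_window = plateau_window, plateau_delta = plateau_delta,
    feature_count_range = as.integer(feature_count_range),
    feature_mutation_prob = feature_mutation_prob,
    max_generations = max_generations,
    restart_max_generations = restart_max_generations,
    seed = as.integer(seed)
  ), class = "iel_config")
}

random_hyper <- function(ranges) {
  vals <- vapply(ranges, function(r) {
    if (r$log) 10^stats::runif(1, log10(r$low), log10(r$high))
    else stats::runif(1, r$low, r$high)
  }, 0)
  stats::setNames(vals, vapply(ranges, `[[`, "", "name"))
}

random_subset <- function(pool, config) {
  lo <- config$feature_count_range[1]
  hi <- min(config$feature_count_range[2], length(pool))
  if (length(pool) < lo) stopf("feature pool smaller than minimum subset size")
  size <- if (hi <= lo) lo else sample(lo:hi, 1L)
  sample(pool, size)
}

new_genome <- function(hyper, subset, lineage) {
  structure(list(hyper = hyper, subset = subset, lineage = lineage),
            class = "iel_genome")
}

genome_key <- function(g) {
  paste(paste(signif(g$hyper, 12), collapse = ","),
        paste(sort(g$subset), collapse = "|"), sep = ";")
}

#' Initialize a random population
#'
#' Hyperparameters are drawn uniformly within their ranges (log-uniform for
#' log-scaled ranges); when a feature pool is supplied, each genome gets a
#' feature subset of uniform random size within the configured range, ids
#' sampled without replacement.
#'
#' @param config an [iel_config()].
#' @param feature_pool candidate feature ids, or `NULL` for
#'   hyperparameter-only search.
#' @param ranges list of [hyper_range()]s.
#' @param n population size override (defaults to `config$pop_size`).
#' @return list of genomes.
#' @export
init_population <- function(config, feature_pool, ranges,
                            n = config$pop_size) {
  if (!is.null(feature_pool) && length(feature_pool) < 2)
    stopf("feature pool must contain at least 2 features")
  lapply(seq_len(n), function(i)
    new_genome(random_hyper(ranges),
               if (is.null(feature_pool)) NULL
               else random_subset(feature_pool, config),
               "random"))
}

#' Recombine two parent genomes
#'
#' Child hyperparameters are the element-wise arithmetic mean of the parents
#' (geometric mean on log-scaled ranges). The child feature subset takes the
#' first half (rounded up) of parent A's subset and the last half (rounded
#' down) of parent B's — a midpoint-pivot crossover — de-duplicated and then
#' padded with random pool draws or truncated into the configured size range.
#'
#' @param a,b parent genomes.
#' @param ranges list of [hyper_range()]s.
#' @param pool feature pool for padding draws.
#' @param config an [iel_config()].
#' @return the child genome (lineage `"recombined"`).
#' @export
recombine <- function(a, b, ranges, pool = NULL, config = iel_config()) {
  hyper <- vapply(seq_along(ranges), function(i) {
    r <- ranges[[i]]
    if (r$log) 10^mean(log10(c(a$hyper[[r$name]], b$hyper[[r$name]])))
    else mean(c(a$hyper[[r$name]], b$hyper[[r$name]]))
  }, 0)
  names(hyper) <- vapply(ranges, `[[`, "", "name")
  subset <- NULL
  if (!is.null(a$subset)) {
    ka <- ceiling(length(a$subset) / 2)
    kb <- floor(length(b$subset) / 2)
    subset <- unique(c(a$subset[seq_len(ka)],
                       if (kb > 0) b$subset[(length(b$subset) - kb + 1):length(b$subset)]))
    lo <- config$feature_count_range[1]
    hi <- config$feature_count_range[2]
    if (length(subset) > hi) subset <- subset[seq_len(hi)]
    if (length(subset) < lo && !is.null(pool)) {
      extra <- setdiff(pool, subset)
      need <- min(lo - length(subset), length(extra))
      if (need > 0) subset <- c(subset, sample(extra, need))
    }
  }
  new_genome(hyper, subset, "recombined")
}

#' Mutate a genome
#'
#' One randomly chosen hyperparameter is shifted by its mutation shift with
#' uniform random sign (on the log10 scale for log ranges) and clipped to its
#' range; with probability `feature_mutation_prob` one feature id is swapped
#' for a random pool feature not currently in the subset.
#'
#' @param g parent genome.
#' @param ranges list of [hyper_range()]s.
#' @param pool feature pool for swaps.
#' @param config an [iel_config()].
#' @return the mutated genome (lineage `"mutated"`).
#' @export
mutate <- function(g, ranges, pool = NULL, config = iel_config()) {
  j <- sample.int(length(ranges), 1L)
  r <- ranges[[j]]
  sign <- sample(c(-1, 1), 1L)
  v <- g$hyper[[r$name]]
  v <- if (r$log) 10^clip(log10(v) + sign * r$shift, log10(r$low), log10(r$high))
       else clip(v + sign * r$shift, r$low, r$high)
  g$hyper[[r$name]] <- v
  if (!is.null(g$subset) && !is.null(pool) &&
      stats::runif(1) < config$feature_mutation_prob) {
    candidates <- setdiff(pool, g$subset)
    if (length(candidates) > 0) {
      pos <- sample.int(length(g$subset), 1L)
      g$subset[pos] <- if (length(candidates) == 1L) candidates
                       else sample(candidates, 1L)
    }
  }
  g$lineage <- "mutated"
  g
}

#' Breed the next generation from a scored population
#'
#' Sorts by BIC (best = lowest), pairs the top `n_recombine_parents` randomly
#' without replacement into recombined children, mutates the next `n_mutate`,
#' discards the rest, and tops up with `n_new_random` fresh random genomes.
#'
#' @param population list of genomes.
#' @param bic numeric vector of fitnesses (lower better).
#' @param config an [iel_config()].
#' @param pool feature pool (or `NULL`).
#' @param ranges list of [hyper_range()]s.
#' @param phase `1` (initial) or `2` (post-restart sizes).
#' @return the next population (size equal to the phase's pop size).
#' @export
breed_next_generation <- function(population, bic, config, pool, ranges,
                                  phase = 1L) {
  sizes <- if (phase == 1L)
    list(pop = config$pop_size, rp = config$n_recombine_parents,
         mut = config$n_mutate, new = config$n_new_random)
  else
    list(pop = config$restart_pop_size, rp = config$restart_recombine_parents,
         mut = config$restart_mutate, new = config$restart_new_random)
  stopifnot(length(population) == length(bic), length(population) >= sizes$rp + sizes$mut)
  ord <- order(bic)
  parents <- population[ord[seq_len(sizes$rp)]]
  pairing <- matrix(sample.int(sizes$rp), ncol = 2)
  children <- lapply(seq_len(nrow(pairing)), function(i)
    recombine(parents[[pairing[i, 1]]], parents[[pairing[i, 2]]],
              ranges, pool, config))
  mut_parents <- population[ord[sizes$rp + seq_len(sizes$mut)]]
  mutants <- lapply(mut_parents, mutate, ranges = ranges, pool = pool,
                    config = config)
  fresh <- init_population(config, pool, ranges, n = sizes$new)
  nxt <- c(children, mutants, fresh)
  if (length(nxt) != sizes$pop)
    stopf("internal bookkeeping error: bred %d genomes, expected %d",
          length(nxt), sizes$pop)
  nxt
}

#' Detect a fitness plateau
#'
#' TRUE iff the relative improvement of the best BIC across the trailing
#' `window` entries of the history (first vs last of those entries) is below
#' `delta`.
#'
#' @param history numeric vector of best-so-far BIC per generation.
#' @param window trailing window length in generations.
#' @param delta minimum relative improvement.
#' @return logical.
#' @export
detect_plateau <- function(history, window = 10, delta = 1e-3) {
  n <- length(history)
  if (n < window) return(FALSE)
  h0 <- history[n - window + 1L]
  h1 <- history[n]
  rel <- (h0 - h1) / max(abs(h0), 1e-12)
  rel < delta
}

#' Fitness-weighted feature importance of the final elite
#'
#' Importance of feature `f` is the softmax(-BIC)-weighted selection
#' frequency of `f` among the elite (best `n_elite`) genomes of the supplied
#' generation: a feature present in every elite genome scores 1, an absent
#' feature 0. The softmax is tempered by the spread (standard deviation) of
#' the elite BICs so that the weights grade across the elite rather than
#' collapsing onto the single best genome whenever BIC gaps are large on the
#' raw scale.
#'
#' @param population list of genomes with subsets.
#' @param bic fitness vector.
#' @param n_elite number of elite genomes to weight (default 60).
#' @param pool feature pool defining the importance vector's support.
#' @return named numeric vector of importances in `[0, 1]`.
#' @export
feature_importance_for_restart <- function(population, bic, n_elite = 60,
                                           pool = NULL) {
  stopifnot(length(population) == length(bic))
  ord <- order(bic)
  elite <- population[ord[seq_len(min(n_elite, length(population)))]]
  eb <- bic[ord[seq_len(length(elite))]]
  temp <- stats::sd(eb[is.finite(eb)])
  if (!is.finite(temp) || temp <= 0) temp <- 1
  w <- softmax_weights(-eb / temp)
  if (is.null(pool))
    pool <- sort(unique(unlist(lapply(elite, `[[`, "subset"))))
  imp <- stats::setNames(numeric(length(pool)), pool)
  for (i in seq_along(elite)) {
    f <- elite[[i]]$subset
    imp[f] <- imp[f] + w[i]
  }
  imp
}

#' Locate the elbow of a fitness-vs-model-size curve
#'
#' Points are sorted by `n_features` and both axes min-max normalized; the
#' elbow is the point with maximum perpendicular distance to the chord
#' joining the first and last points. If all points are collinear, the
#' smallest `n_features` attaining the best (lowest) BIC is returned.
#'
#' @param points data frame or matrix with columns `n_features` and `bic`.
#' @return the `n_features` value at the elbow.
#' @export
find_elbow <- function(points) {
  pts <- as.data.frame(points)
  stopifnot(all(c("n_features", "bic") %in% names(pts)))
  pts <- pts[order(pts$n_features), , drop = FALSE]
  if (nrow(pts) < 3)
    stopf("need at least 3 points to locate an elbow")
  norm01 <- function(v) if (diff(range(v)) == 0) rep(0, length(v))
                        else (v - min(v)) / diff(range(v))
  xx <- norm01(pts$n_features)
  yy <- norm01(pts$bic)
  x1 <- xx[1]; y1 <- yy[1]; x2 <- xx[length(xx)]; y2 <- yy[length(yy)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- if (len == 0) rep(0, length(xx))
       else abs((y2 - y1) * xx - (x2 - x1) * yy + x2 * y1 - y2 * x1) / len
  if (max(d) < 1e-12) {
    best <- min(pts$bic)
    return(min(pts$n_features[pts$bic == best]))
  }
  pts$n_features[which.max(d)]
}

#' Run Integrated Evolutionary Learning
#'
#' Phase 1 evolves `pop_size` genomes until the BIC plateaus. When feature
#' subsets are being evolved, the elbow of the best-BIC-vs-subset-size curve
#' and the elite feature importances then define a warm-restart pool: features
#' with importance at or above the elbow importance plus two standard
#' deviations of the importances (capped at the second-highest importance so
#' the restart pool keeps at least two features). Phase 2 re-initializes a reduced
#' population over that pool and evolves until plateau. The best genome ever
#' evaluated is returned; with a deterministic fitness callback the entire
#' run is reproducible from the seed.
#'
#' @param fitness callback `function(genome) -> list(bic = , ...)`; extra
#'   elements are stored with the best record.
#' @param feature_pool candidate feature ids, or `NULL` to optimize
#'   hyperparameters only (no restart phase).
#' @param config an [iel_config()].
#' @param ranges list of [hyper_range()]s (default [default_hyper_ranges()]).
#' @param verbose print per-generation progress.
#' @return object of class `"iel_fit"`: `best_genome`, `best_fitness`,
#'   `best_bic`, `history` (per-generation logs for both phases),
#'   `importance`, `restart` info, and `n_models` (total evaluated,
#'   summed generation sizes).
#' @export
run_iel <- function(fitness, feature_pool, config = iel_config(),
                    ranges = default_hyper_ranges(), verbose = FALSE) {
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  eval_genome <- function(g) {
    key <- genome_key(g)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rec <- fitness(g)
    if (is.na(rec$bic)) stopf("fitness returned an undefined BIC")
    cache[[key]] <- rec
    rec
  }

  best <- list(genome = NULL, fitness = NULL, bic = Inf)
  n_models <- 0L
  size_curve <- new.env(parent = emptyenv()) # best bic per subset size

  run_phase <- function(pop, phase, max_gen) {
    history <- list()
    best_trace <- numeric(0)
    n_elite <- if (phase == 1L) config$n_elite else config$restart_n_elite
    for (gen in seq_len(max_gen)) {
      recs <- lapply(pop, eval_genome)
      bic <- vapply(recs, `[[`, 0, "bic")
      n_models <<- n_models + length(pop)
      ibest <- which.min(bic)
      if (bic[ibest] < best$bic)
        best <<- list(genome = pop[[ibest]], fitness = recs[[ibest]],
                      bic = bic[ibest])
      if (!is.null(feature_pool)) {
        for (g_i in seq_along(pop)) {
          sz <- as.character(length(pop[[g_i]]$subset))
          cur <- size_curve[[sz]]
          if (is.null(cur) || bic[g_i] < cur) size_curve[[sz]] <- bic[g_i]
        }
      }
      freq <- if (is.null(feature_pool)) NULL else
        table(unlist(lapply(pop, `[[`, "subset"))) / length(pop)
      best_trace <- c(best_trace, best$bic)
      history[[gen]] <- list(generation = gen, phase = phase, bic = bic,
                             best_bic = best$bic,
                             best_genome = pop[[ibest]],
                             pop_size = length(pop),
                             feature_frequency = freq,
                             population = pop)
      if (verbose)
        message(sprintf("phase %d gen %3d: best BIC %.4f (pop %d)",
                        phase, gen, best$bic, length(pop)))
      if (detect_plateau(best_trace, config$plateau_window,
                         config$plateau_delta)) break
      pop <- breed_next_generation(pop, bic, config,
                                   pool = attr(pop, "pool") %||% feature_pool,
                                   ranges = ranges, phase = phase)
    }
    history
  }

  pop1 <- init_population(config, feature_pool, ranges)
  hist1 <- run_phase(pop1, 1L, config$max_generations)

  importance <- NULL
  restart <- list(performed = FALSE, pool = NULL, threshold = NA_real_,
                  elbow = NA_integer_)
  hist2 <- list()
  if (!is.null(feature_pool)) {
    last <- hist1[[length(hist1)]]
    importance <- feature_importance_for_restart(
      last$population, last$bic, n_elite = config$n_elite,
      pool = feature_pool)
    sizes <- as.integer(ls(size_curve))
    curve <- data.frame(n_features = sizes,
                        bic = vapply(as.character(sizes),
                                     function(s) size_curve[[s]], 0))
    if (nrow(curve) >= 3 && length(importance) >= 2) {
      elbow <- find_elbow(curve)
      imp_sorted <- sort(importance, decreasing = TRUE)
      idx <- min(elbow, length(imp_sorted))
      ## cap the threshold at the second-highest importance: the restart is
      ## prescribed, so its pool must retain at least the two most important
      ## features even when the +2 SD shift exceeds every importance
      thr <- min(imp_sorted[idx] + 2 * stats::sd(importance), imp_sorted[2])
      pool2 <- names(importance)[importance >= thr & importance > 0]
      if (length(pool2) < 2) {
        warnf("warm-restart pool has %d feature(s); skipping restart",
              length(pool2))
      } else {
        restart <- list(performed = TRUE, pool = pool2, threshold = thr,
                        elbow = elbow)
        pop2 <- init_population(config, pool2, ranges,
                                n = config$restart_pop_size)
        attr(pop2, "pool") <- pool2
        ## keep phase-2 breeding confined to the restart pool
        old_pool <- feature_pool
        feature_pool <- pool2
        hist2 <- run_phase(pop2, 2L, config$restart_max_generations)
        feature_pool <- old_pool
      }
    }
  }

  structure(list(best_genome = best$genome, best_fitness = best$fitness,
                 best_bic = best$bic,
                 history = c(hist1, hist2),
                 importance = importance, restart = restart,
                 n_models = n_models, config = config),
            class = "iel_fit")
}

#' @export
print.iel_fit <- function(x, ...) {
  gens1 <- sum(vapply(x$history, function(h) h$phase == 1L, TRUE))
  gens2 <- length(x$history) - gens1
  cat("Integrated Evolutionary Learning fit\n")
  cat(sprintf("  best BIC   : %.4f\n", x$best_bic))
  if (!is.null(x$best_genome$subset))
    cat(sprintf("  features   : %d selected [%s%s]\n",
                length(x$best_genome$subset),
                paste(utils::head(sort(x$best_genome$subset), 8), collapse = ", "),
                if (length(x$best_genome$subset) > 8) ", ..." else ""))
  cat(sprintf("  hyper      : %s\n",
              paste(sprintf("%s=%.5g", names(x$best_genome$hyper),
                            x$best_genome$hyper), collapse = ", ")))
  cat(sprintf("  generations: %d (+%d after warm restart); %d models evaluated\n",
              gens1, gens2, x$n_models))
  if (x$restart$performed)
    cat(sprintf("  restart    : pool of %d features at importance >= %.3f (elbow %d)\n",
                length(x$restart$pool), x$restart$threshold, x$restart$elbow))
  invisible(x)
}

#' @export
plot.iel_fit <- function(x, ...) {
  bb <- vapply(x$history, `[[`, 0, "best_bic")
  ph <- vapply(x$history, `[[`, 0L, "phase")
  plot(seq_along(bb), bb, type = "s", xlab = "generation",
       ylab = "best BIC so far", main = "IEL fitness trajectory", ...)
  if (any(ph == 2L))
    graphics::abline(v = which(ph == 2L)[1] - 0.5, lty = 2)
  invisible(x)
}

#' @export
summary.iel_fit <- function(object, ...) {
  df <- data.frame(
    generation = vapply(object$history, `[[`, 0, "generation"),
    phase = vapply(object$history, `[[`, 0L, "phase"),
    pop_size = vapply(object$history, `[[`, 0L, "pop_size"),
    best_bic = vapply(object$history, `[[`, 0, "best_bic"))
  structure(list(trace = df, best_bic = object$best_bic,
                 n_models = object$n_models,
                 restart = object$restart), class = "summary.iel_fit")
}

#' @export
print.summary.iel_fit <- function(x, ...) {
  cat(sprintf("IEL run: %d generations, %d models, best BIC %.4f\n",
              nrow(x$trace), x$n_models, x$best_bic))
  print(utils::head(x$trace, 12))
  invisible(x)
}
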