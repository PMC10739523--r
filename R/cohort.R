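#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical shape of a simulated two-wave adolescent cohort:
#' a psychosocial feature block (mixed nominal/ordinal/continuous, with
#' missing values), a neural feature block (continuous, complete), family
#' structure, demographics, and three CBCL-like subscale T-scores observed at
#' baseline (ages 9-10) and follow-up (ages 11-12). A sparse set of planted
#' features carries the true signal for the follow-up outcome through a
#' liability-threshold model, so that recovery of the planted set can be
#' tested downstream.
#'
#' Defaults mirror the motivating study population: 5,356 unrelated-eligible
#' participants, 763 psychosocial and 5,014 neural candidate features, and
#' T-scores normed to mean 50, SD 10.
#'
#' @param n_participants number of participants.
#' @param n_psychosocial number of psychosocial features.
#' @param n_neural number of neural features.
#' @param frac_nominal fraction of psychosocial features that are nominal.
#' @param frac_ordinal fraction of psychosocial features that are ordinal.
#' @param missing_rate_max per-psychosocial-feature MCAR rate is drawn
#'   uniformly on `[0, missing_rate_max]`.
#' @param n_informative number of planted truly predictive features.
#' @param effect_size signal strength `beta` of the liability model (see
#'   Details); the default 2 is the documented "strong" setting.
#' @param sibling_rate probability that a family has more than one enrolled
#'   child (families have size 1-3).
#' @param tscore_mean,tscore_sd T-score norm parameters.
#' @param rho_waves correlation between baseline and follow-up liabilities.
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"`; under MAR the
#'   per-row missingness odds depend on age.
#' @param seed integer seed; identical config + seed gives identical cohorts.
#'
#' @details The follow-up subscale T-score is generated as
#' \deqn{T_1 = \mu + \sigma \, (\lambda z_{signal} + \sqrt{1-\lambda^2}\, z_{noise}),}
#' where `z_signal` is a standardized equal-magnitude (random sign) linear
#' combination of the planted features and
#' \eqn{\lambda = \beta / \sqrt{1 + \beta^2}} derives from `effect_size`.
#' The marginal T distribution is therefore N(`tscore_mean`, `tscore_sd`)
#' regardless of `effect_size`. The baseline score shares the liability with
#' correlation `rho_waves`.
#'
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 5356,
                          n_psychosocial = 763,
                          n_neural = 5014,
                          frac_nominal = 0.15,
                          frac_ordinal = 0.15,
                          missing_rate_max = 0.30,
                          n_informative = 5,
                          effect_size = 2,
                          sibling_rate = 0.10,
                          tscore_mean = 50,
                          tscore_sd = 10,
                          rho_waves = 0.5,
                          missing_mechanism = c("MCAR", "MAR"),
                          seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (!is_count(n_participants) || n_participants < 2)
    stopf("n_participants must be an integer >= 2")
  if (!is_count(n_psychosocial) || !is_count(n_neural))
    stopf("feature counts must be non-negative integers")
  if (n_psychosocial + n_neural < 1) stopf("need at least one feature")
  if (!is_prob(frac_nominal) || !is_prob(frac_ordinal) ||
      frac_nominal + frac_ordinal > 1)
    stopf("frac_nominal and frac_ordinal must lie in [0,1] and sum to <= 1")
  if (!is_prob(missing_rate_max)) stopf("missing_rate_max must lie in [0,1]")
  if (!is_prob(sibling_rate)) stopf("sibling_rate must lie in [0,1]")
  if (!is_count(n_informative))
    stopf("n_informative must be a non-negative integer")
  if (n_informative > n_psychosocial + n_neural)
    stopf("n_informative exceeds the total number of features")
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0)
    stopf("effect_size must be a single non-negative number")
  if (!is.numeric(tscore_sd) || tscore_sd <= 0) stopf("tscore_sd must be > 0")
  if (!is.numeric(rho_waves) || abs(rho_waves) > 1)
    stopf("rho_waves must lie in [-1,1]")
  structure(list(
    n_participants = as.integer(n_participants),
    n_psychosocial = as.integer(n_psychosocial),
    n_neural = as.integer(n_neural),
    frac_nominal = frac_nominal,
    frac_ordinal = frac_ordinal,
    missing_rate_max = missing_rate_max,
    n_informative = as.integer(n_informative),
    effect_size = effect_size,
    sibling_rate = sibling_rate,
    tscore_mean = tscore_mean,
    tscore_sd = tscore_sd,
    rho_waves = rho_waves,
    missing_mechanism = missing_mechanism,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' The three CBCL-like syndrome subscales used as predictive targets
#' @return character vector of subscale names.
#' @export
subscales <- function() c("attention", "aggressive", "rule_breaking")

#' Generate a synthetic two-wave cohort with planted signal
#'
#' Draws demographics with family/sibling structure, a psychosocial block
#' (mixed variable types, MCAR/MAR missingness injected afterwards), a
#' complete continuous neural block, and baseline/follow-up T-scores for the
#' attention, aggressive and rule-breaking subscales under the
#' liability-threshold model described in [cohort_config()].
#'
#' Categorical (nominal/ordinal) features are stored as integer level codes;
#' `feature_meta` carries the variable type so the preprocessing stack can
#' one-hot encode them. Planted informative features are always continuous.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `cohort` (class `"iel_cohort"`: participants,
#'   features matrix, feature_meta, tscores) and `ground_truth` (planted
#'   feature ids, per-feature effects, liability model description).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n <- config$n_participants

  ## family / sibling structure: sizes 1-3
  fam_sizes <- integer(0)
  total <- 0L
  while (total < n) {
    s <- if (stats::runif(1) < config$sibling_rate)
      sample(c(2L, 3L), 1L, prob = c(0.75, 0.25)) else 1L
    s <- min(s, n - total)
    fam_sizes <- c(fam_sizes, s)
    total <- total + s
  }
  fid <- rep(sprintf("F%05d", seq_along(fam_sizes)), fam_sizes)
  participants <- data.frame(
    pid = sprintf("P%05d", seq_len(n)),
    family_id = fid,
    age_months = sample(107:132, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  ## feature blocks
  p_ps <- config$n_psychosocial
  p_nr <- config$n_neural
  ps_names <- if (p_ps > 0) sprintf("ps%04d", seq_len(p_ps)) else character(0)
  nr_names <- if (p_nr > 0) sprintf("nr%04d", seq_len(p_nr)) else character(0)

  n_nom <- round(config$frac_nominal * p_ps)
  n_ord <- round(config$frac_ordinal * p_ps)
  type_ps <- rep("continuous", p_ps)
  if (p_ps > 0) {
    idx <- sample.int(p_ps)
    type_ps[idx[seq_len(n_nom)]] <- "nominal"
    if (n_ord > 0) type_ps[idx[n_nom + seq_len(n_ord)]] <- "ordinal"
  }

  feat <- matrix(NA_real_, n, p_ps + p_nr,
                 dimnames = list(participants$pid, c(ps_names, nr_names)))
  n_levels <- rep(NA_integer_, p_ps + p_nr)
  for (j in seq_len(p_ps)) {
    feat[, j] <- switch(type_ps[j],
      continuous = stats::rnorm(n),
      nominal = {
        L <- sample(2:5, 1L)
        n_levels[j] <- L
        pr <- stats::rgamma(L, 1); pr <- pr / sum(pr)
        sample.int(L, n, replace = TRUE, prob = pr)
      },
      ordinal = {
        L <- sample(3:5, 1L)
        n_levels[j] <- L
        1L + stats::rbinom(n, L - 1L, stats::runif(1, 0.3, 0.7))
      })
  }
  if (p_nr > 0)
    feat[, p_ps + seq_len(p_nr)] <- stats::rnorm(n * p_nr)

  feature_meta <- data.frame(
    feature = c(ps_names, nr_names),
    modality = rep(c("psychosocial", "neural"), c(p_ps, p_nr)),
    type = c(type_ps, rep("continuous", p_nr)),
    n_levels = n_levels,
    stringsAsFactors = FALSE
  )

  ## planted signal: continuous features only
  cont <- feature_meta$feature[feature_meta$type == "continuous"]
  if (config$n_informative > length(cont))
    stopf("n_informative (%d) exceeds the number of continuous features (%d)",
          config$n_informative, length(cont))
  informative <- sort(sample(cont, config$n_informative))
  k <- length(informative)
  if (k > 0) {
    w <- sample(c(-1, 1), k, replace = TRUE) / sqrt(k)
    z_signal <- as.vector(feat[, informative, drop = FALSE] %*% w)
    z_signal <- as.vector(scale(z_signal))
  } else {
    w <- numeric(0)
    z_signal <- rep(0, n)
  }

  beta <- config$effect_size
  lambda <- beta / sqrt(1 + beta^2)
  rho <- config$rho_waves

  tsc <- data.frame(pid = participants$pid, stringsAsFactors = FALSE)
  for (sc in subscales()) {
    z1 <- lambda * z_signal + sqrt(1 - lambda^2) * stats::rnorm(n)
    z0 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    tsc[[paste0(sc, "_w1")]] <- config$tscore_mean + config$tscore_sd * z1
    tsc[[paste0(sc, "_w0")]] <- config$tscore_mean + config$tscore_sd * z0
  }

  cohort <- structure(list(
    participants = participants,
    features = feat,
    feature_meta = feature_meta,
    tscores = tsc,
    config = config
  ), class = "iel_cohort")

  cohort <- inject_missingness(cohort, config)

  ground_truth <- list(
    informative_feature_ids = informative,
    effects = stats::setNames(lambda * w, informative),
    liability_model = paste0(
      "T1 = mu + sd*(lambda*z_signal + sqrt(1-lambda^2)*noise); ",
      "lambda = ", signif(lambda, 6),
      " from effect_size beta = ", beta,
      "; wave0 correlated rho = ", rho, " with wave1."
    )
  )
  list(cohort = cohort, ground_truth = ground_truth)
}

#' Inject missingness into the psychosocial block
#'
#' Each psychosocial feature receives an independent missingness rate drawn
#' uniformly on `[0, missing_rate_max]`; entries are then masked completely
#' at random (default) or, under the MAR toggle, with row odds tilted by age.
#' When `missing_rate_max > 0.35` the highest draw is pinned at the maximum
#' so at least one feature exceeds the 35% discard threshold and downstream
#' filtering is exercised. Neural features are never touched.
#'
#' @param cohort an `"iel_cohort"`.
#' @param config the [cohort_config()] supplying `missing_rate_max`,
#'   `missing_mechanism` and `seed`.
#' @return the cohort with `NA`s planted in psychosocial columns.
#' @export
inject_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "iel_cohort"))
  rmax <- config$missing_rate_max
  ps <- cohort$feature_meta$feature[cohort$feature_meta$modality == "psychosocial"]
  if (rmax <= 0 || length(ps) == 0) return(cohort)
  n <- nrow(cohort$features)
  rates <- stats::runif(length(ps), 0, rmax)
  if (rmax > 0.35 && !any(rates > 0.35)) rates[which.max(rates)] <- rmax
  if (config$missing_mechanism == "MAR") {
    age <- cohort$participants$age_months
    tilt <- exp(0.5 * as.vector(scale(age)))
  } else {
    tilt <- rep(1, n)
  }
  for (i in seq_along(ps)) {
    pr <- clip(rates[i] * tilt / mean(tilt), 0, 1)
    mask <- stats::runif(n) < pr
    cohort$features[mask, ps[i]] <- NA_real_
  }
  cohort
}

#' @export
print.iel_cohort <- function(x, ...) {
  m <- x$feature_meta
  cat("Synthetic two-wave cohort\n")
  cat(sprintf("  participants : %d (%d families)\n",
              nrow(x$participants), length(unique(x$participants$family_id))))
  cat(sprintf("  features     : %d psychosocial (%d nominal, %d ordinal), %d neural\n",
              sum(m$modality == "psychosocial"),
              sum(m$type == "nominal"), sum(m$type == "ordinal"),
              sum(m$modality == "neural")))
  cat(sprintf("  missingness  : %.1f%% of psychosocial entries\n",
              100 * mean(is.na(x$features[, m$modality == "psychosocial", drop = FALSE]))))
  cat(sprintf("  subscales    : %s, waves 0 and 1\n",
              paste(subscales(), collapse = ", ")))
  invisible(x)
}

## ---- CSV/JSON export with exact numeric round-trip ----

write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- formatC(out[[j]], digits = 17, format = "g")
      s[is.na(out[[j]])] <- ""
      out[[j]] <- trimws(s)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
}

#' Export a cohort (plus ground truth) to CSV/JSON files
#'
#' Writes `participants.csv`, `features.csv`, `feature_meta.csv`,
#' `tscores.csv` and `ground_truth.json` under `path`. Doubles are serialized
#' with 17 significant digits and missing values as empty fields, so
#' [read_cohort()] reproduces the cohort exactly.
#'
#' @param cohort an `"iel_cohort"`.
#' @param ground_truth the planted-signal description from [generate_cohort()].
#' @param path directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
export_cohort <- function(cohort, ground_truth, path) {
  stopifnot(inherits(cohort, "iel_cohort"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stopf("cannot create output directory '%s'", path)
  fdf <- data.frame(pid = rownames(cohort$features),
                    as.data.frame(cohort$features),
                    check.names = FALSE, stringsAsFactors = FALSE)
  files <- file.path(path, c("participants.csv", "features.csv",
                             "feature_meta.csv", "tscores.csv",
                             "ground_truth.json"))
  write_csv_exact(cohort$participants, files[1])
  write_csv_exact(fdf, files[2])
  write_csv_exact(cohort$feature_meta, files[3])
  write_csv_exact(cohort$tscores, files[4])
  jsonlite::write_json(
    list(informative_feature_ids = ground_truth$informative_feature_ids,
         effects = as.list(ground_truth$effects),
         liability_model = ground_truth$liability_model),
    files[5], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Read a cohort previously written by [export_cohort()]
#'
#' @param path directory containing the exported files.
#' @return a list with `cohort` and `ground_truth`, as from [generate_cohort()]
#'   (the config is not round-tripped).
#' @export
read_cohort <- function(path) {
  need <- file.path(path, c("participants.csv", "features.csv",
                            "feature_meta.csv", "tscores.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stopf("missing cohort files: %s", paste(miss, collapse = ", "))
  participants <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  fdf <- utils::read.csv(need[2], check.names = FALSE, stringsAsFactors = FALSE)
  feature_meta <- utils::read.csv(need[3], stringsAsFactors = FALSE)
  tscores <- utils::read.csv(need[4], stringsAsFactors = FALSE)
  feat <- as.matrix(fdf[, -1, drop = FALSE])
  storage.mode(feat) <- "double"
  rownames(feat) <- fdf$pid
  cohort <- structure(list(
    participants = participants, features = feat,
    feature_meta = feature_meta, tscores = tscores, config = NULL
  ), class = "iel_cohort")
  gt_file <- file.path(path, "ground_truth.json")
  ground_truth <- NULL
  if (file.exists(gt_file)) {
    g <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    ground_truth <- list(
      informative_feature_ids = g$informative_feature_ids,
      effects = unlist(g$effects),
      liability_model = g$liability_model
    )
  }
  list(cohort = cohort, ground_truth = ground_truth)
}
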