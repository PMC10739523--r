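#' Construct a feature table
#'
#' Pairs a participant-by-feature numeric matrix (categorical variables as
#' integer level codes, `NA` for missing) with per-feature metadata. The
#' metadata must carry `feature`, `modality` (`psychosocial`/`neural`) and
#' `type` (`nominal`/`ordinal`/`continuous`/`binary`) columns, as produced by
#' [generate_cohort()].
#'
#' @param x numeric matrix with column names.
#' @param meta feature metadata data frame.
#' @return list of class `"feature_table"` with `x`, `meta`, and a `log` of
#'   processing-stage records.
#' @export
feature_table <- function(x, meta) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  meta <- meta[match(colnames(x), meta$feature), , drop = FALSE]
  if (any(is.na(meta$feature)))
    stopf("meta lacks entries for some columns of x")
  if (is.null(meta$source)) meta$source <- meta$feature
  structure(list(x = x, meta = meta, log = list()), class = "feature_table")
}

#' Drop features with too much missingness
#'
#' A feature is kept iff its missing fraction is `<= max_missing`; strictly
#' greater is discarded (so a feature at exactly the threshold survives).
#'
#' @param ft a [feature_table()].
#' @param max_missing maximum tolerated missing fraction (default 0.35).
#' @return the table without the high-missingness columns; the per-feature
#'   missing fractions and drop flags are recorded in `ft$log$missingness`.
#' @export
drop_high_missing <- function(ft, max_missing = 0.35) {
  frac <- colMeans(is.na(ft$x))
  drop <- frac > max_missing
  ft$log$missingness <- data.frame(feature = colnames(ft$x),
                                   missing_frac = unname(frac),
                                   dropped = unname(drop),
                                   stringsAsFactors = FALSE)
  ft$x <- ft$x[, !drop, drop = FALSE]
  ft$meta <- ft$meta[!drop, , drop = FALSE]
  ft
}

#' One-hot encode nominal and ordinal features
#'
#' Every nominal or ordinal feature with `L` observed levels becomes `L`
#' binary indicator columns named `feature=level`; ordinal variables are
#' one-hot encoded too (not integer-coded). A missing value propagates to
#' `NA` in all derived columns. Continuous features pass through unchanged.
#'
#' @param ft a [feature_table()].
#' @param max_levels error if a feature has more observed levels than this
#'   (default 50; usually indicates a mis-tagged id column).
#' @return the encoded table; derived columns carry type `"binary"` and a
#'   `source` pointing at the original feature.
#' @export
encode_one_hot <- function(ft, max_levels = 50) {
  cols <- vector("list", ncol(ft$x))
  metas <- vector("list", ncol(ft$x))
  for (j in seq_len(ncol(ft$x))) {
    nm <- colnames(ft$x)[j]
    ty <- ft$meta$type[j]
    v <- ft$x[, j]
    if (ty %in% c("nominal", "ordinal")) {
      lev <- sort(unique(v[!is.na(v)]))
      if (length(lev) > max_levels)
        stopf("feature '%s' has %d observed levels (> %d); is it an id column?",
              nm, length(lev), max_levels)
      m <- matrix(NA_real_, nrow(ft$x), length(lev),
                  dimnames = list(rownames(ft$x), paste0(nm, "=", lev)))
      ok <- !is.na(v)
      for (l in seq_along(lev)) m[ok, l] <- as.numeric(v[ok] == lev[l])
      cols[[j]] <- m
      metas[[j]] <- data.frame(feature = colnames(m),
                               modality = ft$meta$modality[j],
                               type = "binary", n_levels = NA_integer_,
                               source = nm, stringsAsFactors = FALSE)
    } else {
      cols[[j]] <- ft$x[, j, drop = FALSE]
      metas[[j]] <- ft$meta[j, c("feature", "modality", "type", "n_levels",
                                 "source")]
    }
  }
  ft$x <- do.call(cbind, cols)
  ft$meta <- do.call(rbind, metas)
  rownames(ft$meta) <- NULL
  ft
}

#' Trim (winsorize) continuous features to mean +/- 3 SD
#'
#' Bounds are computed per feature from the observed values of the current
#' partition; values outside are clipped to the bound. Zero-variance features
#' are left unchanged (logged, not warned).
#'
#' @param ft a [feature_table()].
#' @param n_sd number of standard deviations (default 3).
#' @return the trimmed table; bounds and trim counts in `ft$log$trim`.
#' @export
trim_outliers <- function(ft, n_sd = 3) {
  rec <- data.frame(feature = colnames(ft$x), lower = NA_real_,
                    upper = NA_real_, n_trimmed = 0L, constant = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ft$x))) {
    if (!ft$meta$type[j] %in% "continuous") next
    v <- ft$x[, j]
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) { rec$constant[j] <- TRUE; next }
    lo <- mu - n_sd * sdv; hi <- mu + n_sd * sdv
    n_out <- sum(v < lo | v > hi, na.rm = TRUE)
    ft$x[, j] <- clip(v, lo, hi)
    rec$lower[j] <- lo; rec$upper[j] <- hi; rec$n_trimmed[j] <- n_out
  }
  ft$log$trim <- rec
  ft
}

#' Scale all features into [0, 1]
#'
#' Per feature, `x -> (x - min) / (max - min)` over observed values of the
#' current partition; constant features map to 0.
#'
#' @param ft a [feature_table()].
#' @return the scaled table; bounds in `ft$log$scale`.
#' @export
scale_minmax <- function(ft) {
  lo <- suppressWarnings(apply(ft$x, 2, min, na.rm = TRUE))
  hi <- suppressWarnings(apply(ft$x, 2, max, na.rm = TRUE))
  lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- 0
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  ft$x <- sweep(sweep(ft$x, 2, lo, "-"), 2, rng, "/")
  ft$x[, const] <- ifelse(is.na(ft$x[, const]), NA_real_, 0)
  ft$log$scale <- data.frame(feature = colnames(ft$x), min = unname(lo),
                             max = unname(hi), constant = unname(const),
                             stringsAsFactors = FALSE)
  ft
}

#' NNMF-impute the missing entries of a feature table
#'
#' Thin wrapper over [nnmf_impute()] operating on a [feature_table()]; the
#' per-feature imputed-entry counts are logged.
#'
#' @param ft a [feature_table()] with values already scaled to `[0, 1]`.
#' @param rank,max_iter,tol,seed passed to [nnmf_impute()].
#' @return the completed table.
#' @export
impute_table_nnmf <- function(ft, rank = 8, max_iter = 1000, tol = 1e-5,
                              seed = 1L) {
  n_missing <- colSums(is.na(ft$x))
  fit <- nnmf_impute(ft$x, rank = rank, max_iter = max_iter, tol = tol,
                     seed = seed)
  ft$x <- fit$x
  ft$log$impute <- data.frame(feature = colnames(ft$x),
                              n_imputed = unname(n_missing),
                              stringsAsFactors = FALSE)
  ft$log$impute_rank <- fit$rank
  ft
}

#' Agglomerate grouped features into summary indices
#'
#' Within each named instrument group, features are clustered by Ward-linkage
#' hierarchical agglomeration of their (participant-space) profiles and each
#' cluster is replaced by the mean of its members, named `group.k`. Features
#' outside any group pass through. Groups with a single feature pass through
#' unchanged. Intended for psychosocial items lacking instrument summary
#' scores; run after imputation.
#'
#' @param ft a complete (no missing) [feature_table()].
#' @param groups named list mapping group name to member feature names.
#' @param n_clusters clusters per group: a single integer or a named vector
#'   per group; capped at group size.
#' @return the agglomerated table; the member-to-cluster map is logged in
#'   `ft$log$agglomeration`.
#' @export
agglomerate_features <- function(ft, groups, n_clusters = 2) {
  if (anyNA(ft$x)) stopf("agglomeration requires a complete table; impute first")
  in_group <- unlist(groups, use.names = FALSE)
  missing <- setdiff(in_group, colnames(ft$x))
  if (length(missing))
    stopf("group members not present in table: %s", paste(missing, collapse = ", "))
  map <- list()
  new_cols <- list()
  keep <- setdiff(colnames(ft$x), in_group)
  for (g in names(groups)) {
    members <- groups[[g]]
    k <- if (length(n_clusters) > 1) n_clusters[[g]] else n_clusters
    if (length(members) == 1) {
      new_cols[[g]] <- ft$x[, members, drop = FALSE]
      map[[g]] <- data.frame(group = g, feature = members,
                             cluster = members, stringsAsFactors = FALSE)
      next
    }
    k <- max(1L, min(as.integer(k), length(members)))
    hc <- stats::hclust(stats::dist(t(ft$x[, members, drop = FALSE])),
                        method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
    cols <- matrix(0, nrow(ft$x), k,
                   dimnames = list(rownames(ft$x), paste0(g, ".", seq_len(k))))
    for (ci in seq_len(k))
      cols[, ci] <- rowMeans(ft$x[, members[cl == ci], drop = FALSE])
    new_cols[[g]] <- cols
    map[[g]] <- data.frame(group = g, feature = members,
                           cluster = paste0(g, ".", cl),
                           stringsAsFactors = FALSE)
  }
  agg <- do.call(cbind, new_cols)
  meta_keep <- ft$meta[match(keep, ft$meta$feature), , drop = FALSE]
  meta_agg <- data.frame(feature = colnames(agg), modality = "psychosocial",
                         type = "continuous", n_levels = NA_integer_,
                         source = colnames(agg), stringsAsFactors = FALSE)
  ft$x <- cbind(ft$x[, keep, drop = FALSE], agg)
  ft$meta <- rbind(meta_keep, meta_agg)
  rownames(ft$meta) <- NULL
  ft$log$agglomeration <- do.call(rbind, map)
  ft
}

#' Run the full preprocessing stack on one partition
#'
#' Applies, in order: missingness filter, one-hot encoding, outlier trimming,
#' min-max scaling, NNMF imputation, and (optionally) feature agglomeration —
#' to the psychosocial block. Neural features are complete and pre-curated,
#' so they bypass every stage except min-max scaling. All fitted statistics
#' are computed from this partition only; the output has no missing entries
#' and all values in `[0, 1]`.
#'
#' @param x raw participant-by-feature matrix for the partition.
#' @param meta feature metadata (see [feature_table()]).
#' @param max_missing missingness filter threshold.
#' @param nnmf_rank,nnmf_max_iter NNMF settings.
#' @param groups,n_clusters optional agglomeration plan.
#' @param seed seed for the NNMF initialization.
#' @return list of class `"preprocessed_partition"`: `x` (processed matrix),
#'   `meta`, and `report` (a [preprocess_report()]).
#' @export
preprocess_partition <- function(x, meta, max_missing = 0.35,
                                 nnmf_rank = 8, nnmf_max_iter = 500,
                                 groups = NULL, n_clusters = 2, seed = 1L) {
  is_ps <- meta$modality[match(colnames(x), meta$feature)] == "psychosocial"
  out <- list()
  if (any(is_ps)) {
    ft <- feature_table(x[, is_ps, drop = FALSE], meta)
    ft <- drop_high_missing(ft, max_missing)
    ft <- encode_one_hot(ft)
    ft <- trim_outliers(ft)
    ft <- scale_minmax(ft)
    if (anyNA(ft$x))
      ft <- impute_table_nnmf(ft, rank = nnmf_rank, max_iter = nnmf_max_iter,
                              seed = seed)
    if (!is.null(groups)) ft <- agglomerate_features(ft, groups, n_clusters)
    out$ps <- ft
  }
  if (any(!is_ps)) {
    ftn <- feature_table(x[, !is_ps, drop = FALSE], meta)
    ftn <- scale_minmax(ftn)
    out$nr <- ftn
  }
  xx <- do.call(cbind, lapply(out, function(f) f$x))
  mm <- do.call(rbind, lapply(out, function(f) f$meta))
  rownames(mm) <- NULL
  structure(list(x = xx, meta = mm,
                 report = preprocess_report(out)),
            class = "preprocessed_partition")
}

#' Assemble the preprocessing report
#'
#' Collates the per-stage logs (missing fractions, drop flags, trim bounds
#' and counts, scale bounds, imputed counts) into one per-feature table plus
#' the agglomeration map, mirroring a trim-and-fill accounting sheet.
#'
#' @param stages internal list of processed [feature_table()]s.
#' @return list of class `"preprocess_report"` with `features` (data frame)
#'   and `agglomeration`.
#' @export
preprocess_report <- function(stages) {
  rows <- list()
  for (ft in stages) {
    lg <- ft$log
    base <- data.frame(feature = colnames(ft$x), stringsAsFactors = FALSE)
    if (!is.null(lg$trim))
      base <- merge(base, lg$trim, by = "feature", all.x = TRUE, sort = FALSE)
    if (!is.null(lg$scale))
      base <- merge(base, lg$scale[, c("feature", "min", "max")],
                    by = "feature", all.x = TRUE, sort = FALSE)
    if (!is.null(lg$impute))
      base <- merge(base, lg$impute, by = "feature", all.x = TRUE, sort = FALSE)
    dropped <- lg$missingness
    if (!is.null(dropped) && any(dropped$dropped)) {
      extra <- dropped[dropped$dropped, c("feature", "missing_frac"),
                       drop = FALSE]
      extra$dropped <- TRUE
      base <- merge(base, dropped[, c("feature", "missing_frac")],
                    by = "feature", all.x = TRUE, sort = FALSE)
      base$dropped <- FALSE
      for (col in setdiff(names(base), names(extra))) extra[[col]] <- NA
      base <- rbind(base, extra[, names(base)])
    } else if (!is.null(dropped)) {
      base <- merge(base, dropped[, c("feature", "missing_frac")],
                    by = "feature", all.x = TRUE, sort = FALSE)
      base$dropped <- FALSE
    }
    rows[[length(rows) + 1L]] <- base
  }
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA
    r[, all_cols]
  })
  structure(list(features = do.call(rbind, rows),
                 agglomeration = do.call(rbind, lapply(stages, function(f)
                   f$log$agglomeration))),
            class = "preprocess_report")
}

#' Align a processed matrix to a reference feature set
#'
#' Test-partition preprocessing is refit independently, so its one-hot levels
#' or surviving columns can differ from the training partition's. This keeps
#' the reference columns, filling any absent column with 0.
#'
#' @param x processed matrix.
#' @param features reference column names (training order).
#' @return matrix with exactly `features` as columns.
#' @export
align_features <- function(x, features) {
  out <- matrix(0, nrow(x), length(features),
                dimnames = list(rownames(x), features))
  common <- intersect(features, colnames(x))
  out[, common] <- x[, common, drop = FALSE]
  out
}
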