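# Random-forest classifier contract: Gini-split bagged trees with per-split
# feature subsampling, out-of-bag class probabilities, impurity importances
# and repeated-CV tuning.  Backed by ranger; nominal features are passed as
# unordered factors so splits act on category membership.

#' Forest hyper-parameters
#'
#' @param mtry number of randomly selected predictors tried at each split.
#' @param n_trees number of trees (default 1000).
#' @param min_node_size minimal terminal node size (default 1: trees grow
#'   until leaves are pure or singletons).
#' @param sample_fraction per-tree sample: 1 (default) draws a bootstrap
#'   sample with replacement; a value below 1 draws that fraction without
#'   replacement, which leaves more trees out-of-bag per row for the same
#'   computing time.
#' @param seed integer seed making the fit deterministic.
#' @return a `forest_params` list.
#' @export
forest_params <- function(mtry, n_trees = 1000L, min_node_size = 1L,
                          sample_fraction = 1, seed = 1L) {
  stopifnot(mtry >= 1, n_trees >= 1, min_node_size >= 1,
            sample_fraction > 0, sample_fraction <= 1)
  structure(list(
    mtry = as.integer(mtry), n_trees = as.integer(n_trees),
    min_node_size = as.integer(min_node_size),
    sample_fraction = sample_fraction, seed = as.integer(seed)
  ), class = "forest_params")
}

#' Fit a probability random forest
#'
#' Bootstrap-per-tree, Gini impurity splits over `mtry`-subsampled features,
#' trees grown to purity or `min_node_size`.  Out-of-bag probabilities are
#' per-tree class-1 proportions averaged over the trees in which a row was
#' out of bag; the handful of rows (if any) that were in-bag everywhere are
#' filled with the in-sample prediction and counted in `n_missing_oob`.
#'
#' @param features data frame of predictors; nominal ones as factors.
#' @param labels binary 0/1 vector.
#' @param params a [forest_params()] object.
#' @param degenerate_ok allow single-class labels; the fit then predicts the
#'   constant class probability with OOB error 0.
#' @return a `forest_fit`: list with `params`, `oob_prob`, `oob_error`
#'   (Brier form), `gini_importance`, `n_missing_oob`, `model` (the ranger
#'   object or `NULL` for degenerate fits), `feature_names`, `levels_used`.
#' @export
fit_forest <- function(features, labels, params, degenerate_ok = FALSE) {
  stopifnot(inherits(params, "forest_params"))
  features <- as.data.frame(features)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop_eirmrf("labels must be 0/1", "value_error")
  if (nrow(features) < 2) stop_eirmrf("need at least 2 rows", "value_error")
  if (params$mtry > ncol(features)) {
    stop_eirmrf("mtry exceeds the number of features", "parameter_error")
  }

  if (length(unique(labels)) == 1) {
    if (!degenerate_ok) {
      stop_eirmrf("labels are single-class; set degenerate_ok = TRUE", "value_error")
    }
    const <- labels[1]
    return(structure(list(
      params = params,
      oob_prob = rep(const, nrow(features)),
      oob_error = 0,
      gini_importance = stats::setNames(rep(0, ncol(features)), names(features)),
      n_missing_oob = 0L,
      model = NULL,
      constant = const,
      feature_names = names(features)
    ), class = "forest_fit"))
  }

  yf <- factor(labels, levels = c(0, 1))
  frac <- params$sample_fraction %||% 1
  fit <- ranger::ranger(
    x = features, y = yf,
    probability = TRUE,
    num.trees = params$n_trees,
    mtry = params$mtry,
    min.node.size = params$min_node_size,
    replace = frac >= 1,
    sample.fraction = if (frac >= 1) 1 else frac,
    importance = "impurity",
    respect.unordered.factors = "partition",
    seed = params$seed,
    num.threads = 1,
    verbose = FALSE
  )
  oob <- fit$predictions[, "1"]
  n_missing <- sum(is.nan(oob) | is.na(oob))
  if (n_missing > 0) {
    idx <- which(is.nan(oob) | is.na(oob))
    fill <- stats::predict(fit, data = features[idx, , drop = FALSE],
                           num.threads = 1)$predictions[, "1"]
    oob[idx] <- fill
  }
  ff <- structure(list(
    params = params,
    oob_prob = as.numeric(oob),
    oob_error = NA_real_,
    gini_importance = fit$variable.importance,
    n_missing_oob = as.integer(n_missing),
    model = fit,
    constant = NULL,
    feature_names = names(features)
  ), class = "forest_fit")
  ff$oob_error <- oob_brier(ff, labels)
  ff
}

#' Predict class-1 probabilities from a forest fit
#'
#' @param fit a `forest_fit`.
#' @param newdata data frame with the training feature columns.
#' @return probability vector.
#' @export
predict_forest <- function(fit, newdata) {
  stopifnot(inherits(fit, "forest_fit"))
  newdata <- as.data.frame(newdata)
  if (!is.null(fit$constant)) {
    return(rep(fit$constant, nrow(newdata)))
  }
  pr <- stats::predict(fit$model, data = newdata[, fit$feature_names, drop = FALSE],
                       num.threads = 1)
  as.numeric(pr$predictions[, "1"])
}

#' Out-of-bag Brier score of a forest
#'
#' Mean squared difference between the labels and the out-of-bag class-1
#' probabilities.
#'
#' @param fit a `forest_fit`.
#' @param labels the training labels (0/1).
#' @return a scalar in `[0, 1]`.
#' @export
oob_brier <- function(fit, labels) {
  stopifnot(inherits(fit, "forest_fit"))
  p <- fit$oob_prob
  if (length(p) == 0 || all(is.na(p))) {
    stop_eirmrf("no out-of-bag predictions available", "value_error")
  }
  ok <- !is.na(p)
  mean((as.numeric(labels)[ok] - p[ok])^2)
}

#' @export
print.forest_fit <- function(x, ...) {
  cat(sprintf(
    "Probability forest: %d trees, mtry %d, min node size %d (seed %d)\n",
    x$params$n_trees, x$params$mtry, x$params$min_node_size, x$params$seed
  ))
  cat(sprintf("  OOB Brier %.4f; %d features; %d rows lacked OOB trees\n",
              x$oob_error, length(x$feature_names), x$n_missing_oob))
  invisible(x)
}

#' Tune a forest by repeated stratified k-fold cross-validation
#'
#' Evaluates every (`mtry`, `n_trees`) grid cell over `k * repeats`
#' stratified resamples scored by classification accuracy at the 0.5
#' threshold, and returns the cell with the highest mean accuracy; ties are
#' broken toward smaller `mtry`, then fewer trees.  The default grid mirrors
#' common practice for item response features: `mtry` 2--5 and 1000--3000
#' trees in steps of 500.
#'
#' @param features data frame of predictors.
#' @param labels binary 0/1 vector.
#' @param grid list with numeric vectors `mtry` and `n_trees`.
#' @param cv list with `k` (default 10), `repeats` (default 5), `seed`.
#' @param min_node_size passed to each candidate fit.
#' @return list with `best` (a [forest_params()]), `summary` (mean accuracy
#'   per cell) and `resamples` (cell x resample accuracy table).
#' @export
tune_forest <- function(features, labels,
                        grid = list(mtry = 2:5,
                                    n_trees = c(1000, 1500, 2000, 2500, 3000)),
                        cv = list(k = 10, repeats = 5, seed = 1),
                        min_node_size = 1L) {
  features <- as.data.frame(features)
  labels <- as.numeric(labels)
  k <- cv$k %||% 10
  repeats <- cv$repeats %||% 5
  seed <- cv$seed %||% 1
  if (length(grid$mtry) == 0 || length(grid$n_trees) == 0) {
    stop_eirmrf("tuning grid is empty", "parameter_error")
  }
  n <- nrow(features)
  if (k > n) stop_eirmrf("k exceeds the number of rows", "parameter_error")

  cells <- expand.grid(mtry = grid$mtry, n_trees = grid$n_trees)
  res <- vector("list", nrow(cells))
  folds_by_rep <- lapply(seq_len(repeats), function(r) {
    stratified_folds(labels, k, sub_seed(seed, r))
  })
  for (ci in seq_len(nrow(cells))) {
    acc <- numeric(0)
    rep_id <- integer(0)
    fold_id <- integer(0)
    for (r in seq_len(repeats)) {
      folds <- folds_by_rep[[r]]
      for (f in seq_len(k)) {
        test <- which(folds == f)
        train <- setdiff(seq_len(n), test)
        pars <- forest_params(
          mtry = cells$mtry[ci], n_trees = cells$n_trees[ci],
          min_node_size = min_node_size,
          seed = sub_seed(seed, r * 1000 + f)
        )
        fit <- fit_forest(features[train, , drop = FALSE], labels[train], pars)
        p <- predict_forest(fit, features[test, , drop = FALSE])
        acc <- c(acc, mean((p > 0.5) == (labels[test] == 1)))
        rep_id <- c(rep_id, r)
        fold_id <- c(fold_id, f)
      }
    }
    res[[ci]] <- data.frame(
      mtry = cells$mtry[ci], n_trees = cells$n_trees[ci],
      repeat_id = rep_id, fold = fold_id, accuracy = acc
    )
  }
  resamples <- do.call(rbind, res)
  summary <- stats::aggregate(accuracy ~ mtry + n_trees, data = resamples, FUN = mean)
  ord <- order(-summary$accuracy, summary$mtry, summary$n_trees)
  best_row <- summary[ord[1], ]
  list(
    best = forest_params(best_row$mtry, best_row$n_trees,
                         min_node_size = min_node_size, seed = seed),
    summary = summary[order(summary$mtry, summary$n_trees), ],
    resamples = resamples
  )
}

# Stratified fold assignment: each class is spread evenly across folds so no
# fold can end up single-class (as long as each class has >= k members or
# folds tolerate absences).
stratified_folds <- function(labels, k, seed) {
  with_local_seed(seed, {
    folds <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  })
}
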