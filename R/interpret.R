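# Interpretable-ML suite over an arbitrary prediction function: Gini
# importance extraction, partial dependence, accumulated local effects,
# Friedman-Popescu H-statistic, and Spearman agreement scoring.
#
# A "prediction function" here is any function taking a data frame of
# feature rows and returning a numeric vector (probabilities for forests).

#' Prediction function of a forest fit
#'
#' @param fit a `forest_fit`.
#' @return `function(newdata) -> probabilities`.
#' @export
forest_predict_fn <- function(fit) {
  force(fit)
  function(newdata) predict_forest(fit, newdata)
}

#' Ranked Gini importance table
#'
#' @param fit a `forest_fit`.
#' @param normalize scale the top score to 100.
#' @return data frame `feature`, `importance`, sorted decreasing with ties
#'   broken by feature order.
#' @export
gini_importance_table <- function(fit, normalize = FALSE) {
  stopifnot(inherits(fit, "forest_fit"))
  imp <- fit$gini_importance
  out <- data.frame(
    feature = names(imp), importance = as.numeric(imp),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$importance, seq_len(nrow(out))), ]
  rownames(out) <- NULL
  if (normalize && nrow(out) && out$importance[1] > 0) {
    out$importance <- 100 * out$importance / out$importance[1]
  }
  out
}

pd_grid <- function(x, cap = 50) {
  if (is.factor(x) || is.character(x)) {
    return(if (is.factor(x)) levels(x)[levels(x) %in% unique(as.character(x))]
           else sort(unique(as.character(x))))
  }
  u <- sort(unique(x))
  if (length(u) <= cap) u else seq(min(u), max(u), length.out = cap)
}

#' Partial dependence of a prediction function on one feature
#'
#' `PD(g) = mean_rows predict_fn(row with feature forced to g)`, evaluated
#' on a grid of observed values (sorted unique values up to `grid_cap`,
#' equispaced over the range otherwise; category labels for nominal
#' features).
#'
#' @param predict_fn function mapping a feature data frame to predictions.
#' @param data data frame of background rows.
#' @param feature feature name.
#' @param grid optional explicit evaluation grid.
#' @param grid_cap maximal grid size for continuous features (default 50).
#' @return an `effect_curve`: data frame `grid`, `value` with attributes
#'   `feature` and `kind = "pd"`.
#' @export
partial_dependence <- function(predict_fn, data, feature, grid = NULL,
                               grid_cap = 50) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop_eirmrf("empty data", "value_error")
  if (!feature %in% names(data)) {
    stop_eirmrf(sprintf("feature '%s' not in data", feature), "value_error")
  }
  g <- grid %||% pd_grid(data[[feature]], cap = grid_cap)
  n <- nrow(data)
  big <- data[rep(seq_len(n), times = length(g)), , drop = FALSE]
  forced <- rep(g, each = n)
  if (is.factor(data[[feature]])) {
    forced <- factor(forced, levels = levels(data[[feature]]))
  }
  big[[feature]] <- forced
  pred <- predict_fn(big)
  vals <- colMeans(matrix(pred, nrow = n))
  structure(
    data.frame(grid = g, value = vals, stringsAsFactors = FALSE),
    feature = feature, kind = "pd", class = c("effect_curve", "data.frame")
  )
}

#' Accumulated local effects of a continuous feature
#'
#' Quantile bins over the feature; per bin, the mean over in-bin rows of
#' `predict_fn(upper edge) - predict_fn(lower edge)`; cumulative sum across
#' bins; centered so the bin-occupancy-weighted mean effect is zero.
#'
#' @param predict_fn prediction function over feature data frames.
#' @param data data frame of background rows.
#' @param feature continuous feature name.
#' @param n_bins number of quantile bins (default 10).
#' @param edges optional explicit bin edges (overrides `n_bins`), so
#'   empirical curves can be evaluated on the same intervals as a reference.
#' @return an `effect_curve` with `grid` (upper bin edges) and centered
#'   `value`s; attributes `feature`, `kind = "ale"`, `edges`, `weights`.
#' @export
accumulated_local_effects <- function(predict_fn, data, feature, n_bins = 10,
                                      edges = NULL) {
  data <- as.data.frame(data)
  x <- data[[feature]]
  if (is.null(x)) stop_eirmrf(sprintf("feature '%s' not in data", feature), "value_error")
  if (is.factor(x) || is.character(x)) {
    stop_eirmrf("accumulated local effects are defined for continuous features",
                "value_error")
  }
  if (is.null(edges)) {
    if (length(unique(x)) < n_bins + 1) {
      stop_eirmrf("too few distinct values for the requested bins; reduce n_bins",
                  "bin_degeneracy_error")
    }
    edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                    type = 7, names = FALSE))
    if (length(edges) < 3) {
      stop_eirmrf("degenerate quantile bins; reduce n_bins", "bin_degeneracy_error")
    }
  }
  k <- length(edges) - 1
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  # batched evaluation at lower and upper edges of each row's bin
  lo <- data
  hi <- data
  lo[[feature]] <- edges[bin]
  hi[[feature]] <- edges[bin + 1]
  d <- predict_fn(hi) - predict_fn(lo)
  bin_mean <- rep(0, k)
  agg <- tapply(d, factor(bin, levels = seq_len(k)), mean)
  bin_mean[!is.na(agg)] <- agg[!is.na(agg)]
  cum <- cumsum(bin_mean)
  w <- as.numeric(table(factor(bin, levels = seq_len(k)))) / length(x)
  centered <- cum - sum(w * cum)
  structure(
    data.frame(grid = edges[-1], value = centered),
    feature = feature, kind = "ale", edges = edges, weights = w,
    class = c("effect_curve", "data.frame")
  )
}

#' Friedman-Popescu H-statistic
#'
#' Variance-fraction measure of interaction strength, reported as `H^2` in
#' `[0, 1]`.  With one feature `j` the overall statistic compares the full
#' prediction with the sum of the partial-dependence functions of `j` and of
#' all remaining features; with a pair `(j, k)` it compares the joint
#' partial dependence with the two univariate ones.  All functions are
#' mean-centered over the evaluation sample; tiny negative round-off is
#' clipped to 0 (the unclipped value is kept in an attribute).
#'
#' @param predict_fn prediction function over feature data frames.
#' @param data data frame of background rows.
#' @param features one feature name (overall) or two (pairwise).
#' @param n_sample evaluation subsample cap (default 200; pairwise partial
#'   dependence is quadratic in rows).  Use `nrow(data)` for exact results
#'   on small data.
#' @param seed subsampling seed.
#' @return an `h_result`: list with `features`, `value` (clipped `H^2`),
#'   `raw`, `n_sample`.
#' @export
h_statistic <- function(predict_fn, data, features, n_sample = 200, seed = 1L) {
  data <- as.data.frame(data)
  stopifnot(length(features) %in% c(1, 2), all(features %in% names(data)))
  n <- nrow(data)
  if (n_sample < n) {
    idx <- with_local_seed(seed, sample.int(n, n_sample))
    data <- data[idx, , drop = FALSE]
  }
  m <- nrow(data)
  othernames <- setdiff(names(data), features)

  # F[a, b] = f(features from row a, other features from row b)
  cross_eval <- function(feat_cols) {
    a <- rep(seq_len(m), times = m)
    b <- rep(seq_len(m), each = m)
    big <- data[b, , drop = FALSE]
    for (fc in feat_cols) big[[fc]] <- data[[fc]][a]
    matrix(predict_fn(big), nrow = m)   # rows: a (feature source), cols: b
  }

  center <- function(v) v - mean(v)

  if (length(features) == 1) {
    Fj <- cross_eval(features)                 # m x m
    f_full <- predict_fn(data)                 # diagonal of the joint
    pd_j <- rowMeans(Fj)                       # PD_j at each row's x_j
    pd_rest <- colMeans(Fj)                    # PD_{-j} at each row's x_{-j}
    num <- sum((center(f_full) - center(pd_j) - center(pd_rest))^2)
    den <- sum(center(f_full)^2)
  } else {
    Fjk <- cross_eval(features)
    Fj <- cross_eval(features[1])
    Fk <- cross_eval(features[2])
    pd_jk <- rowMeans(Fjk)
    pd_j <- rowMeans(Fj)
    pd_k <- rowMeans(Fk)
    num <- sum((center(pd_jk) - center(pd_j) - center(pd_k))^2)
    den <- sum(center(pd_jk)^2)
  }
  if (den <= .Machine$double.eps) {
    stop_eirmrf("H-statistic undefined: predictions are constant", "value_error")
  }
  raw <- num / den
  structure(list(
    features = features,
    value = min(max(raw, 0), 1),
    raw = raw,
    n_sample = m
  ), class = "h_result")
}

#' @export
print.h_result <- function(x, ...) {
  cat(sprintf("H^2(%s) = %.4f  [n = %d]\n",
              paste(x$features, collapse = ", "), x$value, x$n_sample))
  invisible(x)
}

#' Spearman rank agreement between true and estimated per-feature values
#'
#' Spearman correlation with midranks for ties.  A constant vector makes the
#' correlation undefined; `NA` is returned rather than 0.
#'
#' @param true_values,estimated_values equal-length numeric vectors
#'   (length >= 3).
#' @return rank correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_agreement <- function(true_values, estimated_values) {
  stopifnot(length(true_values) == length(estimated_values))
  if (length(true_values) < 3) {
    stop_eirmrf("need at least 3 paired values", "value_error")
  }
  if (stats::sd(true_values) == 0 || stats::sd(estimated_values) == 0) {
    return(NA_real_)
  }
  suppressWarnings(stats::cor(true_values, estimated_values, method = "spearman"))
}
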