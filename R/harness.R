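# Experiment harnesses: replication of the two simulation studies and the
# end-to-end empirical-style analysis pipeline.

# fit the three model families to one generated response table and score
# them.  EIRM and EIRM-RF are scored on in-sample fitted probabilities
# including the random effects (explanatory use); the forest is scored on
# its out-of-bag probabilities.
fit_and_score <- function(tab, rf_params, eirmrf_control,
                          glmm_control = list(tol = 1e-4, laplace = "profiled")) {
  prepared <- preprocess(tab, center = FALSE)
  y <- prepared$table$y
  person <- prepared$table$person_id
  item <- prepared$table$item_id
  out <- list()

  out$eirm <- tryCatch({
    X <- encode(prepared, "eirm")
    fit <- fit_crossed_logit(y, X, person, item, control = glmm_control)
    p <- predict_prob(fit, X, person, item, include_random = TRUE)
    list(auc = auc(y, p), brier = brier(y, p))
  }, error = function(e) list(error = conditionMessage(e)))

  out$rf <- tryCatch({
    feats <- encode(prepared, "forest")
    fit <- fit_forest(feats, y, rf_params)
    list(auc = auc(y, fit$oob_prob), brier = oob_brier(fit, y))
  }, error = function(e) list(error = conditionMessage(e)))

  out$eirm_rf <- tryCatch({
    fit <- fit_eirm_rf(prepared, rf_params, control = eirmrf_control)
    p <- fit$fitted_prob
    list(auc = auc(y, p), brier = brier(y, p))
  }, error = function(e) list(error = conditionMessage(e)))

  out
}

#' Replicate the model-accuracy simulation study
#'
#' For every condition (fixed-effect structure x random-effect variance x
#' sample size), generates predictor tables and fixed coefficients once,
#' then per replication draws fresh random effects and responses, fits the
#' item response model, the forest and the hybrid to the same data, and
#' aggregates AUC and Brier score means over completed replications.
#'
#' @param reps replications per condition.
#' @param seed master seed; all per-condition and per-replication seeds are
#'   derived from it by counter, so results do not depend on execution
#'   order.
#' @param sizes list of `c(n_persons, n_items)` pairs.
#' @param structures subset of `c("simple", "complex")`.
#' @param variances vector of random-intercept variances (applied to both
#'   factors).
#' @param rf_params forest settings shared by the forest and the hybrid.
#' @param eirmrf_control control list for [fit_eirm_rf()].
#' @param glmm_control control list for the linear item response model fits.
#' @param verbose print per-condition progress.
#' @return data frame: one row per condition x model with mean AUC, mean
#'   Brier, replication counts and failure counts (`invalid` flags
#'   conditions with > 5% failures).
#' @export
run_study1 <- function(reps = 20, seed = 1L,
                       sizes = list(c(100, 10), c(400, 30)),
                       structures = c("simple", "complex"),
                       variances = c(0, 0.7, 2.8),
                       rf_params = forest_params(mtry = 4, n_trees = 500, seed = 1),
                       eirmrf_control = list(max_iter = 10),
                       glmm_control = list(tol = 1e-4, laplace = "profiled"),
                       verbose = FALSE) {
  rows <- list()
  for (si in seq_along(sizes)) {
    sz <- sizes[[si]]
    spec0 <- simulation_spec(n_persons = sz[1], n_items = sz[2])
    tables <- gen_predictors(spec0, seed = sub_seed(seed, 1000 + si))
    for (st in structures) {
      lp <- linear_predictor(tables, st, seed = sub_seed(seed, 2000 + si))
      for (v in variances) {
        acc <- list(eirm = NULL, rf = NULL, eirm_rf = NULL)
        fails <- c(eirm = 0L, rf = 0L, eirm_rf = 0L)
        for (r in seq_len(reps)) {
          rep_seed <- sub_seed(seed, si * 1e6 + match(st, structures) * 1e5 +
                                 round(v * 10) * 1e3 + r)
          tab <- gen_eirm_dataset(tables, lp$eta, v, v, seed = rep_seed)
          pars <- rf_params
          pars$seed <- sub_seed(rep_seed, 3)
          sc <- fit_and_score(tab, pars, eirmrf_control, glmm_control)
          for (m in names(sc)) {
            if (!is.null(sc[[m]]$error)) {
              fails[m] <- fails[m] + 1L
            } else {
              acc[[m]] <- rbind(acc[[m]], c(sc[[m]]$auc, sc[[m]]$brier))
            }
          }
        }
        for (m in names(acc)) {
          n_ok <- if (is.null(acc[[m]])) 0L else nrow(acc[[m]])
          rows[[length(rows) + 1]] <- data.frame(
            n_persons = sz[1], n_items = sz[2], structure = st, sigma2 = v,
            model = m,
            mean_auc = if (n_ok) mean(acc[[m]][, 1]) else NA_real_,
            mean_brier = if (n_ok) mean(acc[[m]][, 2]) else NA_real_,
            n_reps = n_ok, n_fail = fails[[m]],
            invalid = fails[[m]] > 0.05 * reps,
            stringsAsFactors = FALSE
          )
        }
        if (verbose) {
          message(sprintf("study1: %dx%d %s sigma2=%.1f done",
                          sz[1], sz[2], st, v))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# empirical interpretable-ML values of one fitted forest, scored against
# the tree-implied reference values; curves and H-statistics are evaluated
# over the same rows and grids the reference used
score_interpretation <- function(forest_fit, data, truth) {
  pfun <- forest_predict_fn(forest_fit)
  feats <- truth$features
  bg <- data[truth$background_rows, , drop = FALSE]
  hd <- data[truth$h_rows, , drop = FALSE]

  imp <- stats::setNames(rep(0, length(feats)), feats)
  got <- forest_fit$gini_importance[feats]
  imp[!is.na(got)] <- got[!is.na(got)]
  s_imp <- spearman_agreement(truth$importance, imp)

  # curve agreement: product-moment correlation of the (predictor, grid
  # point) values pooled over the selected predictors -- curves are
  # continuous quantities on a common scale, and per-predictor curves can
  # have as few as two points (binary nominals), too short for a
  # correlation of their own.  Per-feature measures (importance, H) use
  # rank correlation instead.
  sel <- truth$selected
  pd_true <- numeric(0)
  pd_emp <- numeric(0)
  for (f in sel) {
    emp <- partial_dependence(pfun, bg, f, grid = truth$pd_grids[[f]])
    pd_true <- c(pd_true, truth$pd[[f]]$value)
    pd_emp <- c(pd_emp, emp$value)
  }
  s_pd <- suppressWarnings(stats::cor(pd_true, pd_emp))

  cont_sel <- intersect(sel, names(truth$ale))
  s_ale <- NA_real_
  if (length(cont_sel)) {
    ale_true <- numeric(0)
    ale_emp <- numeric(0)
    for (f in cont_sel) {
      emp <- accumulated_local_effects(pfun, bg, f, edges = truth$ale_edges[[f]])
      ale_true <- c(ale_true, truth$ale[[f]]$value)
      ale_emp <- c(ale_emp, emp$value)
    }
    s_ale <- suppressWarnings(stats::cor(ale_true, ale_emp))
  }

  h_emp <- vapply(feats, function(f) {
    h_statistic(pfun, hd, f, n_sample = nrow(hd))$value
  }, numeric(1))
  s_h <- spearman_agreement(truth$h, h_emp)

  c(importance = s_imp, pd = s_pd, ale = s_ale, h = s_h)
}

#' Replicate the interpretable-ML recovery study
#'
#' For every condition (predictor correlation x sample size), builds
#' predictor tables and one true tree, computes the tree-implied reference
#' interpretation values, then for each variance level and replication
#' generates tree-truth responses, fits the hybrid and a plain forest, and
#' scores Spearman agreement between empirical and reference values for
#' importance, partial dependence, accumulated local effects and the
#' H-statistic.
#'
#' @param reps replications per condition.
#' @param seed master seed.
#' @param sizes list of `c(n_persons, n_items)` pairs.
#' @param corrs target median predictor correlations.
#' @param variances random-intercept variances (both factors).
#' @param rf_params forest settings.
#' @param eirmrf_control control list for [fit_eirm_rf()].
#' @param h_sample shared H-statistic evaluation rows (reference and
#'   empirical values use the identical rows).
#' @param background_sample shared partial-dependence / ALE background rows.
#' @param truth_mode reference-value definition passed to
#'   [true_interpretation_values()] (default `"rf"`).
#' @param pd_grid_size,ale_bins reference-value resolution.
#' @param verbose print progress.
#' @return data frame: one row per condition x model with mean agreement per
#'   method and failure counts.
#' @export
run_study2 <- function(reps = 50, seed = 1L,
                       sizes = list(c(100, 10)),
                       corrs = c(0.003, 0.4),
                       variances = c(0.7, 2.8),
                       rf_params = forest_params(mtry = 4, n_trees = 500, seed = 1),
                       eirmrf_control = list(max_iter = 10),
                       h_sample = 100, background_sample = 300,
                       truth_mode = "rf",
                       pd_grid_size = 15, ale_bins = 10,
                       verbose = FALSE) {
  rows <- list()
  for (si in seq_along(sizes)) {
    sz <- sizes[[si]]
    for (co in corrs) {
      spec0 <- simulation_spec(n_persons = sz[1], n_items = sz[2],
                               target_median_corr = co)
      cond_seed <- sub_seed(seed, 5000 + si * 100 + round(co * 1000))
      tables <- gen_predictors(spec0, seed = cond_seed)
      tree <- gen_true_tree(tables, seed = sub_seed(cond_seed, 1))
      truth <- true_interpretation_values(
        tree, tables, mode = truth_mode, rf_params = rf_params,
        pd_grid_size = pd_grid_size, ale_bins = ale_bins,
        background_sample = background_sample, h_sample = h_sample,
        seed = sub_seed(cond_seed, 2)
      )
      long_feats <- assemble_long(tables)[, truth$features, drop = FALSE]
      for (v in variances) {
        scores <- list(eirm_rf = NULL, rf = NULL)
        fails <- c(eirm_rf = 0L, rf = 0L)
        for (r in seq_len(reps)) {
          rep_seed <- sub_seed(seed, si * 1e7 + round(co * 1000) * 1e4 +
                                 round(v * 10) * 1e2 + r)
          tab <- gen_eirmtree_dataset(tree, tables, v, v, seed = rep_seed)
          y <- tab$y
          pars <- rf_params
          pars$seed <- sub_seed(rep_seed, 5)

          res_rf <- tryCatch({
            ff <- fit_forest(long_feats, y, pars)
            score_interpretation(ff, long_feats, truth)
          }, error = function(e) NULL)
          if (is.null(res_rf)) fails["rf"] <- fails["rf"] + 1L
          else scores$rf <- rbind(scores$rf, res_rf)

          res_h <- tryCatch({
            fit <- fit_eirm_rf(
              list(features = long_feats, y = y,
                   person_id = tab$person_id, item_id = tab$item_id),
              pars, control = eirmrf_control
            )
            score_interpretation(fit$forest, long_feats, truth)
          }, error = function(e) NULL)
          if (is.null(res_h)) fails["eirm_rf"] <- fails["eirm_rf"] + 1L
          else scores$eirm_rf <- rbind(scores$eirm_rf, res_h)
        }
        for (m in names(scores)) {
          sm <- scores[[m]]
          n_ok <- if (is.null(sm)) 0L else nrow(sm)
          mns <- if (n_ok) colMeans(sm, na.rm = TRUE) else
            c(importance = NA, pd = NA, ale = NA, h = NA)
          rows[[length(rows) + 1]] <- data.frame(
            n_persons = sz[1], n_items = sz[2], corr = co, sigma2 = v,
            model = m,
            importance = mns[["importance"]], pd = mns[["pd"]],
            ale = mns[["ale"]], h = mns[["h"]],
            n_reps = n_ok, n_fail = fails[[m]],
            invalid = fails[[m]] > 0.05 * reps,
            stringsAsFactors = FALSE
          )
        }
        if (verbose) {
          message(sprintf("study2: %dx%d corr=%.3f sigma2=%.1f done",
                          sz[1], sz[2], co, v))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end explanatory analysis of a person-by-item dataset
#'
#' Reproduces the full modeling pipeline on user-supplied long-format data:
#' preprocessing report, null (intercept-only) crossed model with its
#' conditional ICCs, the linear-effects item response model with a Wald
#' coefficient table, an optionally tuned forest, the hybrid fit, an
#' accuracy comparison of all three, and the interpretation suite on the
#' hybrid's forest component.
#'
#' @param source data frame or CSV path (see [load_long_table()]).
#' @param schema an `eirmrf_schema`.
#' @param rf_params forest settings used when `tune_grid` is `NULL`.
#' @param tune_grid optional list(`mtry`, `n_trees`) grid; when supplied the
#'   forest is tuned by repeated stratified CV first.
#' @param tune_cv CV settings for tuning (default 10-fold, 5 repeats).
#' @param eirmrf_control control list for [fit_eirm_rf()].
#' @param interpret compute the interpretation suite (default `TRUE`).
#' @param h_sample row cap for H-statistics.
#' @param seed master seed.
#' @return a list report: `prepared`, `icc_null`, `eirm` (fit +
#'   coefficient table), `forest`, `tuning`, `eirm_rf`, `accuracy` (data
#'   frame for the three models), `unexplained`, `interpretation`.
#' @export
analyze_empirical <- function(source, schema,
                              rf_params = forest_params(mtry = 4, n_trees = 500),
                              tune_grid = NULL,
                              tune_cv = list(k = 10, repeats = 5),
                              eirmrf_control = list(),
                              interpret = TRUE, h_sample = 100, seed = 1L) {
  tab <- if (inherits(source, "response_table")) source else
    load_long_table(source, schema)
  prepared <- preprocess(tab)
  y <- prepared$table$y
  person <- prepared$table$person_id
  item <- prepared$table$item_id

  # null model: intercept-only crossed random intercepts -> conditional ICCs
  null_fit <- fit_crossed_logit(
    y, matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
    person, item
  )
  icc_null <- c(person = conditional_icc(null_fit$sigma2_person),
                item = conditional_icc(null_fit$sigma2_item))

  X <- encode(prepared, "eirm")
  eirm_fit <- fit_crossed_logit(y, X, person, item)
  coef_table <- data.frame(
    term = names(eirm_fit$beta),
    estimate = as.numeric(eirm_fit$beta),
    se = eirm_fit$se,
    z = as.numeric(eirm_fit$beta) / eirm_fit$se,
    stringsAsFactors = FALSE
  )
  coef_table$p_value <- 2 * stats::pnorm(-abs(coef_table$z))
  p_eirm <- predict_prob(eirm_fit, X, person, item, include_random = TRUE)

  feats <- encode(prepared, "forest")
  tuning <- NULL
  if (!is.null(tune_grid)) {
    tune_cv$seed <- tune_cv$seed %||% sub_seed(seed, 21)
    tuning <- tune_forest(feats, y, grid = tune_grid, cv = tune_cv)
    rf_params <- tuning$best
  }
  rf_params$seed <- sub_seed(seed, 22)
  rf_fit <- fit_forest(feats, y, rf_params)

  hy_control <- utils::modifyList(list(bernoulli_seed = sub_seed(seed, 23)),
                                  eirmrf_control)
  hybrid <- fit_eirm_rf(prepared, rf_params, control = hy_control)

  accuracy <- rbind(
    accuracy_report(y, p_eirm, "eirm"),
    accuracy_report(y, rf_fit$oob_prob, "rf_oob"),
    accuracy_report(y, predict_forest(rf_fit, feats), "rf_insample"),
    accuracy_report(y, hybrid$fitted_prob, "eirm_rf")
  )

  interpretation <- NULL
  if (interpret) {
    pfun <- forest_predict_fn(hybrid$forest)
    fnames <- names(feats)
    cont <- fnames[!vapply(feats, is.factor, logical(1))]
    importance <- gini_importance_table(hybrid$forest, normalize = TRUE)
    pd <- lapply(stats::setNames(fnames, fnames), function(f) {
      partial_dependence(pfun, feats, f, grid_cap = 20)
    })
    ale <- lapply(stats::setNames(cont, cont), function(f) {
      accumulated_local_effects(pfun, feats, f, n_bins = 10)
    })
    h_overall <- vapply(stats::setNames(fnames, fnames), function(f) {
      h_statistic(pfun, feats, f, n_sample = h_sample,
                  seed = sub_seed(seed, 31))$value
    }, numeric(1))
    top <- names(sort(h_overall, decreasing = TRUE))[1]
    h_pairs <- vapply(stats::setNames(setdiff(fnames, top), setdiff(fnames, top)),
                      function(f) {
      h_statistic(pfun, feats, c(top, f), n_sample = h_sample,
                  seed = sub_seed(seed, 32))$value
    }, numeric(1))
    interpretation <- list(
      importance = importance, pd = pd, ale = ale,
      h_overall = h_overall, h_pairwise_top = list(feature = top, h = h_pairs)
    )
  }

  list(
    prepared = prepared,
    null_fit = null_fit,
    icc_null = icc_null,
    eirm = list(fit = eirm_fit, coefficients = coef_table),
    forest = rf_fit,
    tuning = tuning,
    eirm_rf = hybrid,
    accuracy = accuracy,
    unexplained = unexplained_variability(hybrid),
    interpretation = interpretation
  )
}
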