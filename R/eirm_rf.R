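# The hybrid estimator: a random forest supplies the fixed part of a
# crossed random-intercept logistic model; the two components are estimated
# by alternating fits until the forest's out-of-bag error stabilizes.

#' Dichotomize combined response/probability values into a target outcome
#'
#' For each row, `v = y + p` combines the observed binary response with the
#' current fitted probability.  The target outcome is 0 when `v < 0.5`,
#' 1 when `v > 1.5` (both "aligned" cases, where the target equals the
#' observed response), and a Bernoulli(`p`) draw when `0.5 <= v <= 1.5`.
#'
#' @param y binary 0/1 vector.
#' @param p fitted probabilities in `[0, 1]`.
#' @param seed integer seed for the Bernoulli draws.
#' @return binary vector of target outcomes.
#' @export
make_target_outcome <- function(y, p, seed = 1L) {
  y <- as.numeric(y)
  p <- as.numeric(p)
  stopifnot(length(y) == length(p))
  if (any(p < 0 | p > 1)) {
    stop_eirmrf("probabilities must lie in [0, 1]", "value_error")
  }
  v <- y + p
  out <- integer(length(y))
  out[v > 1.5] <- 1L
  mid <- v >= 0.5 & v <= 1.5
  if (any(mid)) {
    draws <- with_local_seed(seed, stats::rbinom(sum(mid), 1, p[mid]))
    out[mid] <- draws
  }
  out
}

#' Fit the forest / mixed-model hybrid
#'
#' Alternates (1) a probability forest on the current target outcome, giving
#' out-of-bag predictions `p_rf`, and (2) a crossed random-intercept
#' logistic model of the observed responses on `(1, p_rf)`, giving the
#' intercept `gamma0`, slope `gamma1` and the person/item variance
#' components.  The composed fitted probability
#' `invlogit(gamma0 + gamma1 * p_rf + theta_j + b_i)` drives the next target
#' outcome.  Iterations stop when the forest's out-of-bag Brier score
#' changes by less than `tol` between successive iterations.
#'
#' @param prepared a `prepared_data` object from [preprocess()], or a list
#'   with elements `features` (data frame), `y`, `person_id`, `item_id`.
#' @param rf_params a [forest_params()] object (the forest seed anchors the
#'   per-iteration forest substreams).
#' @param control list: `tol` (default `1e-4`), `max_iter` (default 50),
#'   `bernoulli_seed` (default 2), `glmm_control` passed through to
#'   [fit_crossed_logit()].
#' @return an `eirmrf_fit`: list with `forest` (final `forest_fit`), `glmm`
#'   (final `eirmrf_glmm` with coefficients `gamma0`, `gamma1`), `p_rf`
#'   (final out-of-bag forest probabilities), `fitted_prob`, `trace`
#'   (per-iteration OOB Brier), `n_iter`, `converged`, `seeds`, plus the
#'   training frame pieces needed for prediction.
#' @export
fit_eirm_rf <- function(prepared, rf_params, control = list()) {
  ctrl <- utils::modifyList(list(
    tol = 1e-4, max_iter = 50L, bernoulli_seed = 2L,
    # iterations use the fast profiled Laplace flavor; the returned mixed
    # model is refit once at full Laplace after the loop ends unless
    # final_full is disabled
    glmm_control = list(tol = 1e-5, laplace = "profiled"),
    final_full = TRUE
  ), control)

  if (inherits(prepared, "prepared_data")) {
    features <- encode(prepared, "forest")
    y <- prepared$table$y
    person <- prepared$table$person_id
    item <- prepared$table$item_id
  } else {
    features <- as.data.frame(prepared$features)
    y <- as.numeric(prepared$y)
    person <- prepared$person_id
    item <- prepared$item_id
  }
  if (length(unique(y)) < 2) {
    stop_eirmrf("responses are single-class", "value_error")
  }

  target <- y
  trace <- numeric(0)
  converged <- FALSE
  forest <- NULL
  glmm <- NULL
  p_rf <- NULL
  fitted <- NULL
  glmm_ctrl <- ctrl$glmm_control

  n_iter <- 0L
  for (t in seq_len(ctrl$max_iter)) {
    n_iter <- t
    pars_t <- rf_params
    pars_t$seed <- sub_seed(rf_params$seed, t)
    forest <- fit_forest(features, target, pars_t, degenerate_ok = TRUE)
    p_rf <- forest$oob_prob
    glmm <- fit_crossed_logit(
      y, cbind(`(Intercept)` = 1, p_rf = p_rf), person, item,
      control = glmm_ctrl
    )
    # warm-start the next mixed-model fit from this one
    glmm_ctrl$start <- list(
      beta = glmm$beta, sigma2 = pmax(c(glmm$sigma2_person, glmm$sigma2_item), 1e-3)
    )
    th <- glmm$person_modes[as.character(person)]
    bi <- glmm$item_modes[as.character(item)]
    fitted <- invlogit(glmm$beta[1] + glmm$beta[2] * p_rf +
                         as.numeric(th) + as.numeric(bi))
    trace[t] <- oob_brier(forest, target)
    if (t >= 2 && abs(trace[t] - trace[t - 1]) < ctrl$tol) {
      converged <- TRUE
      break
    }
    target <- make_target_outcome(y, fitted, seed = sub_seed(ctrl$bernoulli_seed, t))
    if (length(unique(target)) < 2) {
      # degenerate target: the forest step would be single-class; stop here
      break
    }
  }
  if (!converged) {
    warning("EIRM-RF did not meet the OOB-error stabilization rule within ",
            n_iter, " iterations", call. = FALSE)
  }

  if (isTRUE(ctrl$final_full)) {
    # final mixed-model refit at full Laplace so the reported gamma and
    # variance components carry the exact-likelihood quality
    glmm_ctrl$laplace <- "full"
    glmm <- fit_crossed_logit(
      y, cbind(`(Intercept)` = 1, p_rf = p_rf), person, item, control = glmm_ctrl
    )
    th <- glmm$person_modes[as.character(person)]
    bi <- glmm$item_modes[as.character(item)]
    fitted <- invlogit(glmm$beta[1] + glmm$beta[2] * p_rf +
                         as.numeric(th) + as.numeric(bi))
  }

  structure(list(
    forest = forest,
    glmm = glmm,
    p_rf = p_rf,
    fitted_prob = as.numeric(fitted),
    trace = trace,
    n_iter = n_iter,
    converged = converged,
    seeds = list(forest = rf_params$seed, bernoulli = ctrl$bernoulli_seed),
    y = y,
    person_id = as.character(person),
    item_id = as.character(item),
    feature_names = names(features)
  ), class = "eirmrf_fit")
}

#' Predict from a fitted hybrid model
#'
#' `invlogit(gamma0 + gamma1 * p_rf(row) + theta_j + b_i)`, where `p_rf` is
#' the forest's predicted probability for the row's features, and the random
#' terms are included per `include_random` (unseen persons/items contribute
#' 0 on the logit scale).
#'
#' @param fit an `eirmrf_fit`.
#' @param features data frame of feature rows (training encoding).
#' @param person_id,item_id cluster identifiers of the rows.
#' @param include_random include conditional modes (default `TRUE`).
#' @return probability vector.
#' @export
predict_eirm_rf <- function(fit, features, person_id = NULL, item_id = NULL,
                            include_random = TRUE) {
  stopifnot(inherits(fit, "eirmrf_fit"))
  p_rf <- predict_forest(fit$forest, features)
  eta <- fit$glmm$beta[1] + fit$glmm$beta[2] * p_rf
  if (include_random) {
    if (is.null(person_id) || is.null(item_id)) {
      stop_eirmrf("person_id and item_id are required when include_random = TRUE",
                  "design_error")
    }
    th <- fit$glmm$person_modes[as.character(person_id)]
    bi <- fit$glmm$item_modes[as.character(item_id)]
    th[is.na(th)] <- 0
    bi[is.na(bi)] <- 0
    eta <- eta + as.numeric(th) + as.numeric(bi)
  }
  invlogit(as.numeric(eta))
}

#' Share of latent-response variance left unexplained by the forest part
#'
#' On the latent logistic scale the fitted model decomposes variance into
#' the explained part `Var(gamma1 * p_rf)` and the unexplained part
#' `sigma2_person + sigma2_item + pi^2 / 3` (random intercepts plus the
#' logistic residual).  The default definition reports
#' `(sigma2_person + sigma2_item + pi^2/3) / (Var(gamma1 p_rf) + sigma2_person + sigma2_item + pi^2/3)`.
#' The `"random_effects"` alternative reports only the random-intercept
#' share, `(sigma2_person + sigma2_item)` over the same total.
#'
#' @param fit an `eirmrf_fit`.
#' @param definition `"total"` (default) or `"random_effects"`.
#' @return scalar in `[0, 1]`, with the definition recorded in the
#'   `"definition"` attribute.
#' @export
unexplained_variability <- function(fit, definition = c("total", "random_effects")) {
  definition <- match.arg(definition)
  stopifnot(inherits(fit, "eirmrf_fit"))
  v_fix <- stats::var(fit$glmm$beta[2] * fit$p_rf)
  s2 <- fit$glmm$sigma2_person + fit$glmm$sigma2_item
  total <- v_fix + s2 + pi^2 / 3
  val <- switch(definition,
    total = (s2 + pi^2 / 3) / total,
    random_effects = s2 / total
  )
  structure(as.numeric(val), definition = definition)
}

#' @export
print.eirmrf_fit <- function(x, ...) {
  cat("EIRM-RF hybrid fit\n")
  cat(sprintf("  iterations: %d (%s); final forest OOB Brier %.4f\n",
              x$n_iter, if (x$converged) "converged" else "not converged",
              x$trace[length(x$trace)]))
  cat(sprintf("  gamma0 = %.3f, gamma1 = %.3f\n", x$glmm$beta[1], x$glmm$beta[2]))
  cat(sprintf("  sigma2_person = %.3f, sigma2_item = %.3f%s\n",
              x$glmm$sigma2_person, x$glmm$sigma2_item,
              if (x$glmm$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Export a hybrid fit summary as JSON
#'
#' @param fit an `eirmrf_fit`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
eirmrf_summary_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "eirmrf_fit"))
  out <- list(
    gamma0 = unname(fit$glmm$beta[1]),
    gamma1 = unname(fit$glmm$beta[2]),
    sigma2_person = fit$glmm$sigma2_person,
    sigma2_item = fit$glmm$sigma2_item,
    icc_person = conditional_icc(fit$glmm$sigma2_person),
    icc_item = conditional_icc(fit$glmm$sigma2_item),
    trace = fit$trace,
    n_iter = fit$n_iter,
    converged = fit$converged,
    unexplained_variability = as.numeric(unexplained_variability(fit)),
    seeds = fit$seeds
  )
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
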