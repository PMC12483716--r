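test_that("target outcome follows the three split-function branches", {
  # aligned cases are deterministic
  expect_equal(make_target_outcome(1, 0.9), 1L)   # v = 1.9 > 1.5
  expect_equal(make_target_outcome(0, 0.2), 0L)   # v = 0.2 < 0.5
  expect_equal(make_target_outcome(c(1, 0, 1), c(0.99, 0.01, 0.8)),
               c(1L, 0L, 1L))
  # middle branch is a Bernoulli(p) draw with the fitted probability
  n <- 10000
  draws <- make_target_outcome(rep(0, n), rep(0.9, n), seed = 99)
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(mean(draws) - 0.9), 3 * se)
  # seeded determinism
  expect_identical(make_target_outcome(rep(0, 50), rep(0.6, 50), seed = 5),
                   make_target_outcome(rep(0, 50), rep(0.6, 50), seed = 5))
  expect_error(make_target_outcome(1, 1.2), class = "value_error")
})

test_that("combined value stays in [0, 2] and branches cover it", {
  set.seed(301)
  y <- rbinom(200, 1, 0.5)
  p <- runif(200)
  v <- y + p
  expect_true(all(v >= 0 & v <= 2))
  out <- make_target_outcome(y, p, seed = 1)
  expect_true(all(out %in% c(0L, 1L)))
  expect_true(all(out[v > 1.5] == 1L))
  expect_true(all(out[v < 0.5] == 0L))
})

test_that("the hybrid fit is seeded-deterministic and traces OOB error", {
  prep <- small_sim_prepared(seed = 7)
  pars <- forest_params(mtry = 3, n_trees = 80, seed = 11)
  ctrl <- list(max_iter = 3, glmm_control = list(tol = 1e-5))
  f1 <- suppressWarnings(fit_eirm_rf(prep, pars, control = ctrl))
  f2 <- suppressWarnings(fit_eirm_rf(prep, pars, control = ctrl))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$fitted_prob, f2$fitted_prob)
  expect_equal(length(f1$trace), f1$n_iter)
  expect_true(all(f1$trace >= 0 & f1$trace <= 1))
  expect_true(all(f1$fitted_prob >= 0 & f1$fitted_prob <= 1))
  expect_named(f1$glmm$beta, c("(Intercept)", "p_rf"))
  # convergence rule: |last - previous| < tol when converged
  if (f1$converged) {
    k <- f1$n_iter
    expect_lt(abs(f1$trace[k] - f1$trace[k - 1]), 1e-4)
  }
})

test_that("zero-variance truth drives the variance estimates to the boundary", {
  # strong single continuous effect, no random effects in the truth
  set.seed(303)
  J <- 100; I <- 10
  person <- rep(sprintf("p%03d", 1:J), each = I)
  item <- rep(sprintf("i%02d", 1:I), J)
  x <- rnorm(J)[match(person, sprintf("p%03d", 1:J))]
  feats <- data.frame(x = x, z = rnorm(J * I))
  y <- rbinom(J * I, 1, plogis(2 * x))
  hits <- 0L
  for (s in 1:3) {
    fit <- suppressWarnings(fit_eirm_rf(
      list(features = feats, y = y, person_id = person, item_id = item),
      forest_params(mtry = 1, n_trees = 100, seed = s),
      control = list(max_iter = 2, glmm_control = list(tol = 1e-5))
    ))
    if (fit$glmm$sigma2_person + fit$glmm$sigma2_item < 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("hybrid predictions compose the forest and the random effects", {
  prep <- small_sim_prepared(seed = 9)
  fit <- suppressWarnings(fit_eirm_rf(
    prep, forest_params(mtry = 3, n_trees = 60, seed = 2),
    control = list(max_iter = 2, glmm_control = list(tol = 1e-5))
  ))
  feats <- encode(prep, "forest")
  # fixed-part predictions are identical for rows with identical features
  p_fixed <- predict_eirm_rf(fit, feats[c(1, 1, 2), ], include_random = FALSE)
  expect_equal(p_fixed[1], p_fixed[2])
  # null composition: gamma = 0 gives 0.5 everywhere
  fit0 <- fit
  fit0$glmm$beta[] <- 0
  expect_true(all(predict_eirm_rf(fit0, feats[1:5, ], include_random = FALSE) == 0.5))
  # monotone in the forest probability when gamma1 > 0
  fitm <- fit
  fitm$glmm$beta <- c(0, 2)
  grid <- feats[rep(1, 3), ]
  pr <- predict_forest(fit$forest, grid)
  expect_true(all(diff(invlogit(fitm$glmm$beta[1] + fitm$glmm$beta[2] *
                                  sort(pr))) >= 0))
  # unseen clusters fall back to the population level
  p_new <- predict_eirm_rf(fit, feats[1, , drop = FALSE],
                           person_id = "nobody", item_id = "nothing")
  p_pop <- predict_eirm_rf(fit, feats[1, , drop = FALSE], include_random = FALSE)
  expect_equal(p_new, p_pop)
})

test_that("with the slope pinned at zero the mixed model reduces to the
           intercept-only crossed fit", {
  prep <- small_sim_prepared(seed = 13)
  y <- prep$table$y
  person <- prep$table$person_id
  item <- prep$table$item_id
  # oracle: intercept-only crossed model
  ref <- fit_crossed_logit(y, matrix(1, length(y), 1), person, item)
  # the procedure's mixed-model step with an uninformative forest
  # probability column reduces to the intercept-only crossed model
  set.seed(99)
  p_flat <- 0.5 + rnorm(length(y), 0, 1e-3)
  fit <- fit_crossed_logit(y, cbind(1, p_rf = p_flat), person, item)
  expect_equal(fit$sigma2_person, ref$sigma2_person, tolerance = 1e-2)
  expect_equal(fit$sigma2_item, ref$sigma2_item, tolerance = 1e-2)
})

test_that("unexplained variability follows the latent variance decomposition", {
  prep <- small_sim_prepared(seed = 15)
  fit <- suppressWarnings(fit_eirm_rf(
    prep, forest_params(mtry = 3, n_trees = 60, seed = 3),
    control = list(max_iter = 2, glmm_control = list(tol = 1e-5))
  ))
  # toy arithmetic check under the default definition
  toy <- fit
  toy$glmm$sigma2_person <- 0.7
  toy$glmm$sigma2_item <- 0.7
  # engineer Var(gamma1 * p_rf) = 2
  toy$glmm$beta <- c(0, sqrt(2 / stats::var(fit$p_rf)))
  expected <- (1.4 + pi^2 / 3) / (2 + 1.4 + pi^2 / 3)
  expect_equal(as.numeric(unexplained_variability(toy)), expected,
               tolerance = 1e-10)
  # nothing explained -> 1
  toy$glmm$beta <- c(0, 0)
  toy$glmm$sigma2_person <- 0
  toy$glmm$sigma2_item <- 0
  expect_equal(as.numeric(unexplained_variability(toy)), 1)
  # alternative definition recorded in metadata
  u <- unexplained_variability(fit, "random_effects")
  expect_equal(attr(u, "definition"), "random_effects")
  expect_true(u >= 0 && u <= 1)
})

test_that("rank-deficient edge: the variance share vanishes as the explained
           part dominates", {
  prep <- small_sim_prepared(seed = 17)
  fit <- suppressWarnings(fit_eirm_rf(
    prep, forest_params(mtry = 3, n_trees = 60, seed = 4),
    control = list(max_iter = 2, glmm_control = list(tol = 1e-5))
  ))
  big <- fit
  big$glmm$beta <- c(0, 1e6)
  expect_lt(as.numeric(unexplained_variability(big)), 1e-6)
})
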