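test_that("forest fit honors the contract on shapes, seeds and degenerate labels", {
  set.seed(201)
  n <- 120
  d <- data.frame(a = rnorm(n), b = rnorm(n),
                  g = factor(sample(c("u", "v", "w"), n, TRUE)))
  y <- rbinom(n, 1, plogis(d$a))
  pars <- forest_params(mtry = 2, n_trees = 100, seed = 42)
  f1 <- fit_forest(d, y, pars)
  f2 <- fit_forest(d, y, pars)
  expect_identical(f1$oob_prob, f2$oob_prob)
  expect_true(all(f1$oob_prob >= 0 & f1$oob_prob <= 1))
  expect_true(all(f1$gini_importance >= 0))
  expect_equal(sort(names(f1$gini_importance)), sort(names(d)))

  expect_error(fit_forest(d, y, forest_params(mtry = 9, n_trees = 10)),
               class = "parameter_error")

  # single-class labels with the degenerate flag
  f0 <- fit_forest(d, rep(0, n), pars, degenerate_ok = TRUE)
  expect_true(all(f0$oob_prob == 0))
  expect_equal(f0$oob_error, 0)
  expect_error(fit_forest(d, rep(0, n), pars), class = "value_error")
})

test_that("forests fit pure interactions: XOR reaches training accuracy 1", {
  base <- expand.grid(x1 = c(0, 1), x2 = c(0, 1))
  d <- base[rep(1:4, each = 50), ]
  set.seed(202)
  d$x1 <- d$x1 + rnorm(200, 0, 0.05)
  d$x2 <- d$x2 + rnorm(200, 0, 0.05)
  y <- as.numeric(xor(d$x1 > 0.5, d$x2 > 0.5))
  fit <- fit_forest(d, y, forest_params(mtry = 2, n_trees = 200,
                                        min_node_size = 1, seed = 7))
  p <- predict_forest(fit, d)
  expect_equal(mean((p > 0.5) == (y == 1)), 1)
})

test_that("OOB Brier matches the hand formula", {
  fit <- structure(list(oob_prob = c(0.8, 0.4, 0.6)), class = "forest_fit")
  expect_equal(oob_brier(fit, c(1, 0, 1)), (0.04 + 0.16 + 0.16) / 3)
  fit2 <- structure(list(oob_prob = c(1, 0)), class = "forest_fit")
  expect_equal(oob_brier(fit2, c(1, 0)), 0)
  fit3 <- structure(list(oob_prob = rep(0.5, 4)), class = "forest_fit")
  expect_equal(oob_brier(fit3, c(0, 1, 0, 1)), 0.25)
  fit4 <- structure(list(oob_prob = numeric(0)), class = "forest_fit")
  expect_error(oob_brier(fit4, numeric(0)), class = "value_error")
})

test_that("OOB error stabilizes as trees accumulate", {
  set.seed(203)
  n <- 150
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * d$a - d$b))
  briers <- sapply(c(100, 400, 1600), function(nt) {
    fit_forest(d, y, forest_params(mtry = 2, n_trees = nt, seed = 99))$oob_error
  })
  gaps <- abs(diff(briers))
  expect_lt(gaps[2], max(gaps[1], 1e-4))
})

test_that("an informative feature out-ranks pure noise in nearly all seeds", {
  set.seed(204)
  n <- 150
  wins <- 0L
  for (s in 1:20) {
    d <- data.frame(signal = rnorm(n), noise = rnorm(n))
    y <- as.numeric(d$signal + rnorm(n, 0, 0.5) > 0)
    fit <- fit_forest(d, y, forest_params(mtry = 1, n_trees = 100, seed = s))
    imp <- fit$gini_importance
    wins <- wins + (imp["signal"] > imp["noise"])
  }
  expect_gte(wins, 19)
})

test_that("tuning evaluates the grid by repeated stratified CV", {
  set.seed(205)
  n <- 80
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * d$a))

  # singleton grid returns that cell
  res1 <- tune_forest(d, y, grid = list(mtry = 2, n_trees = 50),
                      cv = list(k = 5, repeats = 2, seed = 1))
  expect_equal(res1$best$mtry, 2L)
  expect_equal(res1$best$n_trees, 50L)
  # bookkeeping: k x repeats rows per cell
  expect_equal(nrow(res1$resamples), 10)

  res2 <- tune_forest(d, y, grid = list(mtry = 1:2, n_trees = c(50, 100)),
                      cv = list(k = 4, repeats = 2, seed = 2))
  expect_equal(nrow(res2$summary), 4)
  expect_equal(nrow(res2$resamples), 4 * 8)
  expect_true(res2$best$mtry %in% 1:2)

  # stratification: every fold sees both classes
  folds <- eirmrf:::stratified_folds(y, 5, 1)
  both <- sapply(1:5, function(f) length(unique(y[folds == f])))
  expect_true(all(both == 2))

  expect_error(tune_forest(d, y, grid = list(mtry = integer(0), n_trees = 100)),
               class = "parameter_error")
})
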