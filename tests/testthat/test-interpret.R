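# brute-force oracles for the suite live in helper-oracles.R

test_that("partial dependence equals brute-force averaging on a tiny fixture", {
  set.seed(101)
  d <- data.frame(x1 = rnorm(5), x2 = rnorm(5),
                  g = factor(c("a", "b", "a", "b", "a")))
  # arbitrary tabulated nonlinear prediction rule
  f <- function(df) {
    plogis(0.8 * df$x1 - df$x2^2 + ifelse(df$g == "a", 0.5, -0.3) +
             0.6 * df$x1 * (df$g == "b"))
  }
  grid <- c(-1, 0, 1)
  pd <- partial_dependence(f, d, "x1", grid = grid)
  expect_equal(pd$value, brute_pd(f, d, "x1", grid), tolerance = 1e-12)
  pd_g <- partial_dependence(f, d, "g")
  expect_equal(pd_g$value, brute_pd(f, d, "g", c("a", "b")), tolerance = 1e-12)
  # constant prediction -> flat curve
  pd_c <- partial_dependence(function(df) rep(0.3, nrow(df)), d, "x2")
  expect_true(all(pd_c$value == 0.3))
  # additive rule: PD over x1 is the rule itself up to its x2 part
  f_add <- function(df) plogis(df$x1)
  pd_a <- partial_dependence(f_add, d, "x1", grid = grid)
  expect_equal(pd_a$value, plogis(grid))
  expect_error(partial_dependence(f, d[0, ], "x1"), class = "value_error")
})

test_that("accumulated local effects match brute force and are centered", {
  set.seed(102)
  d <- data.frame(x = runif(9), z = rnorm(9))
  f <- function(df) df$x^2 + 0.5 * df$z
  a <- accumulated_local_effects(f, d, "x", n_bins = 3)
  expect_equal(a$value, brute_ale(f, d, "x", attr(a, "edges")), tolerance = 1e-12)
  expect_lt(abs(sum(attr(a, "weights") * a$value)), 1e-12)

  # linear function: slope between consecutive edges is the coefficient
  f_lin <- function(df) 2 * df$x
  a_lin <- accumulated_local_effects(f_lin, d, "x", n_bins = 4)
  e <- attr(a_lin, "edges")
  expect_equal(diff(a_lin$value) / diff(e[-1]), rep(2, 3), tolerance = 1e-10)

  # constant function: all-zero curve
  a_c <- accumulated_local_effects(function(df) rep(1, nrow(df)), d, "x", n_bins = 3)
  expect_true(all(abs(a_c$value) < 1e-14))

  expect_error(accumulated_local_effects(f, d, "x", n_bins = 50),
               class = "bin_degeneracy_error")
  dg <- d; dg$x <- factor(letters[1:9])
  expect_error(accumulated_local_effects(f, dg, "x"), class = "value_error")
})

test_that("ALE of an additive function matches centered PD under independence", {
  set.seed(103)
  d <- data.frame(x = seq(0.02, 0.98, length.out = 40), z = rnorm(40))
  f <- function(df) plogis(2 * df$x - 1) + 0.3 * df$z
  a <- accumulated_local_effects(f, d, "x", n_bins = 8)
  pd_at_edges <- partial_dependence(f, d, "x", grid = a$grid)
  w <- attr(a, "weights")
  pd_centered <- pd_at_edges$value - sum(w * pd_at_edges$value)
  expect_lt(max(abs(a$value - pd_centered)), 0.02)
})

test_that("H-statistic matches brute force and detects pure interaction", {
  set.seed(104)
  d <- data.frame(x1 = rnorm(6), x2 = rnorm(6), x3 = rnorm(6))
  f <- function(df) plogis(df$x1 * df$x2 + 0.5 * df$x3)
  h <- h_statistic(f, d, "x1", n_sample = 6)
  expect_equal(h$raw, brute_h_overall(f, d, "x1"), tolerance = 1e-10)
  hp <- h_statistic(f, d, c("x1", "x2"), n_sample = 6)
  expect_equal(hp$raw, brute_h_pair(f, d, "x1", "x2"), tolerance = 1e-10)

  # additive function -> raw statistic at numerical zero before clipping
  f_add <- function(df) df$x1 + exp(df$x2) - df$x3^2
  for (feat in c("x1", "x2")) {
    expect_lt(abs(h_statistic(f_add, d, feat, n_sample = 6)$raw), 1e-8)
  }
  expect_lt(abs(h_statistic(f_add, d, c("x1", "x3"), n_sample = 6)$raw), 1e-8)

  # pure multiplicative interaction on the symmetric grid: all variance is
  # interaction, H^2 = 1
  g <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1))
  hx <- h_statistic(function(df) df$x1 * df$x2, g, c("x1", "x2"), n_sample = 4)
  expect_equal(hx$value, 1, tolerance = 1e-12)

  expect_error(h_statistic(function(df) rep(1, nrow(df)), d, "x1", n_sample = 6),
               class = "value_error")
  expect_true(h_statistic(f, d, "x1", n_sample = 6)$value >= 0)
  expect_true(h_statistic(f, d, "x1", n_sample = 6)$value <= 1)
})

test_that("Spearman agreement uses midranks and flags degenerate input", {
  expect_equal(spearman_agreement(1:5, 1:5), 1)
  expect_equal(spearman_agreement(1:5, 5:1), -1)
  expect_equal(spearman_agreement(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_agreement(rep(1, 4), 1:4)))
  expect_error(spearman_agreement(1:2, 1:2), class = "value_error")
})

test_that("importance table ranks a determining feature first after a refit", {
  set.seed(105)
  n <- 400
  d <- data.frame(x1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                  n4 = rnorm(n), n5 = rnorm(n))
  y <- as.numeric(d$x1 > 0)
  fit <- fit_forest(d, y, forest_params(mtry = 2, n_trees = 200, seed = 9))
  tab <- gini_importance_table(fit)
  expect_equal(tab$feature[1], "x1")
  tabn <- gini_importance_table(fit, normalize = TRUE)
  expect_equal(tabn$importance[1], 100)
  expect_true(all(diff(tabn$importance) <= 0))
})
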