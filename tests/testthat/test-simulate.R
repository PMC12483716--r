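test_that("predictor generation is seeded, calibrated and well-shaped", {
  spec <- simulation_spec(100, 10, target_median_corr = 0.003)
  t1 <- gen_predictors(spec, seed = 42)
  t2 <- gen_predictors(spec, seed = 42)
  expect_identical(t1$person, t2$person)
  expect_identical(t1$item, t2$item)
  expect_equal(ncol(t1$person), 13)
  expect_equal(ncol(t1$item), 3)
  expect_equal(nrow(t1$person), 100)
  # achieved median near the small target
  expect_lte(abs(t1$achieved$median), 0.05)
  # continuous columns close to standard normal
  cont <- t1$person[grep("^pcon", names(t1$person))]
  for (v in cont) {
    expect_lt(abs(mean(v)), 3 / sqrt(100))
    expect_lt(abs(var(v) - 1), 3 * sqrt(2 / 99))
  }
  # nominal columns are 2- or 3-level factors
  noms <- t1$person[grep("^pnom", names(t1$person))]
  expect_true(all(vapply(noms, nlevels, 1L) %in% 2:3))
})

test_that("the medium correlation target is achieved", {
  spec <- simulation_spec(100, 10, target_median_corr = 0.4)
  t1 <- gen_predictors(spec, seed = 52)
  expect_lte(abs(t1$achieved$median - 0.4), 0.05)
})

test_that("the fixed linear predictor is additive for simple structure and
           interactive for complex", {
  spec <- simulation_spec(60, 8)
  tabs <- gen_predictors(spec, seed = 5)
  lp_s <- linear_predictor(tabs, "simple", seed = 3)
  lp_c <- linear_predictor(tabs, "complex", seed = 3)
  long <- eirmrf:::assemble_long(tabs)
  feats <- long[, c(names(tabs$person), names(tabs$item))]

  # the generating surface as a function of features; consistency check
  # against the tabulated eta on observed rows
  f_s <- linear_predictor_fn(lp_s)
  pj <- rep(seq_len(60), each = 8)
  ii <- rep(seq_len(8), times = 60)
  expect_equal(f_s(feats), lp_s$eta[cbind(pj, ii)], tolerance = 1e-12,
               ignore_attr = TRUE)

  # a person predictor paired with an item predictor: no interaction under
  # the simple truth, interaction present under the complex truth
  # (first 5 persons crossed with all 8 items, so every item level appears)
  sub <- feats[1:40, ]
  h_s <- h_statistic(f_s, sub, c("pcon1", "inom1"), n_sample = nrow(sub))
  expect_lt(h_s$raw, 1e-10)
  f_c <- linear_predictor_fn(lp_c)
  h_c <- vapply(paste0("pcon", 1:4), function(p) {
    h_statistic(f_c, sub, c(p, "inom1"), n_sample = nrow(sub))$raw
  }, numeric(1))
  expect_gt(max(h_c), 1e-6)

  # forcing all coefficients to zero nulls the surface
  lp0 <- lp_s
  lp0$coefficients$beta_person[] <- 0
  lp0$coefficients$beta_item[] <- 0
  eta0 <- 0 +
    outer(as.numeric(eirmrf:::dummy_code(tabs$person) %*%
                       lp0$coefficients$beta_person),
          as.numeric(eirmrf:::dummy_code(tabs$item) %*%
                       lp0$coefficients$beta_item), `+`)
  expect_true(all(eta0 == 0))
})

test_that("response generation matches the latent model", {
  spec <- simulation_spec(200, 10)
  tabs <- gen_predictors(spec, seed = 6)
  eta0 <- matrix(0, 200, 10,
                 dimnames = list(rownames(tabs$person), rownames(tabs$item)))
  # eta = 0, no variance -> mean response 0.5
  tab <- gen_eirm_dataset(tabs, eta0, 0, 0, seed = 9)
  expect_lt(abs(mean(tab$y) - 0.5), 3 * 0.5 / sqrt(2000))
  expect_s3_class(tab, "response_table")
  expect_equal(nrow(tab), 2000)
  # seeded determinism and fresh random effects per seed
  tab2 <- gen_eirm_dataset(tabs, eta0, 0.7, 0.7, seed = 11)
  tab3 <- gen_eirm_dataset(tabs, eta0, 0.7, 0.7, seed = 11)
  expect_identical(tab2$y, tab3$y)
  re2 <- attr(tab2, "random_effects")
  re4 <- attr(gen_eirm_dataset(tabs, eta0, 0.7, 0.7, seed = 12), "random_effects")
  expect_false(identical(re2$theta, re4$theta))
  # generated random effects have the requested scale
  expect_lt(abs(var(re2$theta) - 0.7), 3 * 0.7 * sqrt(2 / 199))
})

test_that("true trees use only selected features and honest leaves", {
  spec <- simulation_spec(100, 10)
  tabs <- gen_predictors(spec, seed = 21)
  tree <- gen_true_tree(tabs, seed = 33)
  expect_length(tree$sel_item, 2)
  expect_length(tree$sel_person, 5)
  expect_true(tree$depth %in% 3:5)
  expect_identical(serialize_tree(tree),
                   serialize_tree(gen_true_tree(tabs, seed = 33)))

  long <- eirmrf:::assemble_long(tabs)
  feats <- long[, c(names(tabs$person), names(tabs$item))]
  p <- predict_tree(tree, feats)
  expect_true(all(p > 0.05 - 1e-12 & p < 0.95 + 1e-12))

  # probing an unselected feature never changes the prediction
  unselected <- setdiff(names(feats), tree$selected)
  probe <- feats[1:50, ]
  for (f in unselected[1:3]) {
    probe2 <- probe
    probe2[[f]] <- if (is.factor(probe[[f]])) {
      factor(levels(probe[[f]])[1], levels = levels(probe[[f]]))
    } else probe[[f]] + 10
    expect_identical(predict_tree(tree, probe), predict_tree(tree, probe2))
  }
})

test_that("tree-truth responses respect the gamma mapping", {
  spec <- simulation_spec(150, 10)
  tabs <- gen_predictors(spec, seed = 23)
  tree <- gen_true_tree(tabs, seed = 24)
  tab <- gen_eirmtree_dataset(tree, tabs, 0.7, 0.7, seed = 25)
  expect_equal(nrow(tab), 1500)
  expect_identical(tab$y, gen_eirmtree_dataset(tree, tabs, 0.7, 0.7, seed = 25)$y)

  # gamma1 = 0 makes outcomes independent of the tree
  tree0 <- tree
  tree0$gamma1 <- 0
  tree0$gamma0 <- 0
  tab0 <- gen_eirmtree_dataset(tree0, tabs, 0, 0, seed = 26)
  expect_lt(abs(mean(tab0$y) - 0.5), 3 * 0.5 / sqrt(1500))
  p_tree <- attr(tab0, "p_tree")
  expect_lt(abs(cor(tab0$y, p_tree)), 0.08)
})

test_that("tree-implied reference interpretation values behave as designed", {
  spec <- simulation_spec(80, 8)
  tabs <- gen_predictors(spec, seed = 27)
  tree <- gen_true_tree(tabs, seed = 28)
  truth <- true_interpretation_values(tree, tabs, mode = "tree", h_sample = 120)

  unselected <- setdiff(truth$features, tree$selected)
  expect_true(all(truth$importance[unselected] == 0))
  expect_true(any(truth$importance[tree$selected] > 0))
  # flat reference PD for unselected features
  for (f in unselected[1:2]) {
    expect_lt(diff(range(truth$pd[[f]]$value)), 1e-12)
  }
  # PD values equal brute-force summation on a subsample
  long <- eirmrf:::assemble_long(tabs)
  feats <- long[, truth$features]
  f_sel <- tree$selected[1]
  sub <- feats[1:20, ]
  pf <- function(df) predict_tree(tree, df)
  bf <- brute_pd(pf, sub, f_sel, truth$pd_grids[[f_sel]])
  pd_sub <- partial_dependence(pf, sub, f_sel, grid = truth$pd_grids[[f_sel]])
  expect_equal(pd_sub$value, bf, tolerance = 1e-12)

  # a single-split tree is additive: every pairwise H is zero
  chain <- tree
  chain$root <- list(type = "split", feature = tree$selected[3],
                     threshold = 0,
                     left = list(type = "leaf", prob = 0.2),
                     right = list(type = "leaf", prob = 0.8))
  if (is.factor(feats[[tree$selected[3]]])) {
    chain$root$left_cats <- levels(feats[[tree$selected[3]]])[1]
    chain$root$threshold <- NULL
  }
  pc <- function(df) predict_tree(chain, df)
  h <- h_statistic(pc, feats[1:40, ], c(tree$selected[3], tree$selected[1]),
                   n_sample = 40)
  expect_lt(h$raw, 1e-10)
})

test_that("large generated samples reproduce the implied latent intraclass
           correlation", {
  # J = 2000 persons: refitting the null crossed model on data generated at
  # sigma2 = 0.7 recovers the closed-form conditional ICC
  J <- 2000; I <- 20
  pid <- rep(seq_len(J), each = I)
  iid <- rep(seq_len(I), times = J)
  set.seed(606)
  th <- rnorm(J, 0, sqrt(0.7))
  b <- rnorm(I, 0, sqrt(0.7))
  y <- rbinom(J * I, 1, plogis(th[pid] + b[iid]))
  fit <- fit_crossed_logit(y, matrix(1, J * I, 1), pid, iid,
                           control = list(tol = 1e-4, laplace = "profiled"))
  expect_lt(abs(conditional_icc(fit$sigma2_person) - conditional_icc(0.7)),
            0.035)
})
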