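# Independent oracles and shared fixtures, kept deliberately naive so they
# stay independent of the implementation paths they check.

# plain Newton-Raphson IRLS for logistic regression, written from the
# textbook recursion
irls_logistic <- function(y, X, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * w), t(X) %*% (y - mu))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# brute-force partial dependence by explicit double loop
brute_pd <- function(predict_fn, data, feature, grid) {
  unname(sapply(grid, function(g) {
    tot <- 0
    for (r in seq_len(nrow(data))) {
      row <- data[r, , drop = FALSE]
      row[[feature]] <- if (is.factor(data[[feature]])) {
        factor(g, levels = levels(data[[feature]]))
      } else g
      tot <- tot + predict_fn(row)
    }
    tot / nrow(data)
  }))
}

# brute-force ALE: per-bin averaged local differences, cumulated, centered
brute_ale <- function(predict_fn, data, feature, edges) {
  x <- data[[feature]]
  k <- length(edges) - 1
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  bm <- numeric(k)
  for (j in seq_len(k)) {
    idx <- which(bin == j)
    if (!length(idx)) next
    d <- 0
    for (r in idx) {
      hi <- data[r, , drop = FALSE]; hi[[feature]] <- edges[j + 1]
      lo <- data[r, , drop = FALSE]; lo[[feature]] <- edges[j]
      d <- d + (predict_fn(hi) - predict_fn(lo))
    }
    bm[j] <- d / length(idx)
  }
  cum <- cumsum(bm)
  w <- tabulate(bin, nbins = k) / length(x)
  cum - sum(w * cum)
}

# brute-force overall H^2 by explicit double loops over the sample
brute_h_overall <- function(predict_fn, data, feature) {
  n <- nrow(data)
  f <- numeric(n); pdj <- numeric(n); pdmj <- numeric(n)
  for (i in seq_len(n)) f[i] <- predict_fn(data[i, , drop = FALSE])
  for (i in seq_len(n)) {
    sj <- 0; smj <- 0
    for (k in seq_len(n)) {
      row <- data[k, , drop = FALSE]
      row[[feature]] <- data[[feature]][i]
      sj <- sj + predict_fn(row)
      row2 <- data[i, , drop = FALSE]
      row2[[feature]] <- data[[feature]][k]
      smj <- smj + predict_fn(row2)
    }
    pdj[i] <- sj / n
    pdmj[i] <- smj / n
  }
  c <- function(v) v - mean(v)
  sum((c(f) - c(pdj) - c(pdmj))^2) / sum(c(f)^2)
}

brute_h_pair <- function(predict_fn, data, f1, f2) {
  n <- nrow(data)
  pjk <- numeric(n); pj <- numeric(n); pk <- numeric(n)
  for (i in seq_len(n)) {
    s_jk <- 0; s_j <- 0; s_k <- 0
    for (k in seq_len(n)) {
      row <- data[k, , drop = FALSE]
      row[[f1]] <- data[[f1]][i]; row[[f2]] <- data[[f2]][i]
      s_jk <- s_jk + predict_fn(row)
      row <- data[k, , drop = FALSE]; row[[f1]] <- data[[f1]][i]
      s_j <- s_j + predict_fn(row)
      row <- data[k, , drop = FALSE]; row[[f2]] <- data[[f2]][i]
      s_k <- s_k + predict_fn(row)
    }
    pjk[i] <- s_jk / n; pj[i] <- s_j / n; pk[i] <- s_k / n
  }
  c <- function(v) v - mean(v)
  sum((c(pjk) - c(pj) - c(pk))^2) / sum(c(pjk)^2)
}

# deterministic crossed binary fixture; the frozen reference values in
# test-glmm.R were produced by an independent mixed-model Laplace fit on
# exactly these draws
crossed_fixture <- function() {
  set.seed(4242)
  J <- 40; I <- 5
  pid <- rep(1:J, each = I)
  iid <- rep(1:I, J)
  th <- rnorm(J, 0, sqrt(0.8))
  b <- rnorm(I, 0, sqrt(0.4))
  x1 <- rnorm(J * I)
  x2 <- rbinom(J * I, 1, 0.5)
  eta <- -0.2 + 0.9 * x1 + 0.5 * x2 + th[pid] + b[iid]
  y <- rbinom(J * I, 1, plogis(eta))
  list(y = y, X = cbind(`(Intercept)` = 1, x1 = x1, x2 = x2),
       pid = pid, iid = iid)
}

# small long-format table with a schema, used across data-prep tests
toy_schema <- function() {
  predictor_schema(list(
    list(name = "ability", level = "person", kind = "continuous"),
    list(name = "grade", level = "person", kind = "nominal",
         categories = c("g5", "g8"), reference = "g5"),
    list(name = "format", level = "item", kind = "nominal",
         categories = c("mc", "open", "tf"), reference = "mc"),
    list(name = "effort", level = "person_by_item", kind = "continuous")
  ))
}

toy_table_df <- function() {
  persons <- data.frame(
    person_id = c("p1", "p2", "p3", "p4"),
    ability = c(-1, 0, 0.5, 2),
    grade = c("g5", "g8", "g5", "g8"),
    stringsAsFactors = FALSE
  )
  items <- data.frame(
    item_id = c("i1", "i2", "i3"),
    format = c("mc", "open", "tf"),
    stringsAsFactors = FALSE
  )
  df <- merge(persons, items)
  set.seed(77)
  df$effort <- round(rnorm(nrow(df)), 3)
  df$response <- rep(c(0, 1), length.out = nrow(df))
  df[order(df$person_id, df$item_id), ]
}

# small simulated prepared dataset for model-level tests
small_sim_prepared <- function(seed = 5, n_persons = 60, n_items = 8,
                               sigma2 = 0.7, structure = "simple") {
  spec <- simulation_spec(n_persons, n_items, structure = structure,
                          sigma2_person = sigma2, sigma2_item = sigma2)
  tabs <- gen_predictors(spec, seed = seed)
  lp <- linear_predictor(tabs, structure, seed = seed + 1)
  tab <- gen_eirm_dataset(tabs, lp$eta, sigma2, sigma2, seed = seed + 2)
  preprocess(tab, center = FALSE)
}
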