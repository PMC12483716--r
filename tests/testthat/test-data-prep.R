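test_that("loading validates, listwise-deletes and types the long table", {
  sch <- toy_schema()
  df <- toy_table_df()

  tab <- load_long_table(df, sch)
  expect_s3_class(tab, "response_table")
  expect_equal(nrow(tab), 12)
  expect_equal(attr(tab, "n_persons"), 4)
  expect_equal(attr(tab, "n_items"), 3)
  expect_true(is.factor(tab$grade))
  expect_equal(levels(tab$format), c("mc", "open", "tf"))

  # one missing predictor value -> that row silently dropped
  df_na <- df
  df_na$effort[5] <- NA
  tab_na <- load_long_table(df_na, sch)
  expect_equal(nrow(tab_na), 11)

  # domain and consistency errors
  df_bad <- df; df_bad$response[1] <- 2
  expect_error(load_long_table(df_bad, sch), class = "value_error")
  df_dup <- rbind(df, df[1, ])
  expect_error(load_long_table(df_dup, sch), class = "value_error")
  df_inc <- df; df_inc$ability[df_inc$person_id == "p1"][1] <- 99
  expect_error(load_long_table(df_inc, sch), class = "consistency_error")
  expect_error(load_long_table(df[, -4], sch), class = "schema_error")
})

test_that("round-trip through CSV reproduces the table exactly", {
  sch <- toy_schema()
  tab <- load_long_table(toy_table_df(), sch)
  path <- tempfile(fileext = ".csv")
  write_response_table(tab, path)
  tab2 <- load_long_table(path, sch)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("preprocessing centers, screens near-zero variance, reports correlations", {
  sch <- predictor_schema(list(
    list(name = "a", level = "person_by_item", kind = "continuous"),
    list(name = "b", level = "person_by_item", kind = "continuous"),
    list(name = "flat", level = "person_by_item", kind = "continuous")
  ))
  n <- 30
  df <- data.frame(
    person_id = rep(sprintf("p%d", 1:6), each = 5),
    item_id = rep(sprintf("i%d", 1:5), 6),
    response = rep(c(0, 1), 15),
    a = rep(c(1, 2, 3), 10),
    b = seq_len(n) / 10,
    flat = rep(7, n)
  )
  prep <- preprocess(load_long_table(df, sch))
  expect_equal(prep$dropped$predictor, "flat")
  expect_equal(sort(unique(prep$table$a)), c(-1, 0, 1))
  expect_lt(abs(mean(prep$table$b)), 1e-10)
  expect_equal(prep$centers[["a"]], 2)

  # two copies of the same predictor -> correlation 1 reported and flagged
  df$flat <- df$a
  prep2 <- preprocess(load_long_table(df, sch))
  expect_true("a:flat" %in% prep2$correlation$high_pairs)

  # all predictors dropped -> error
  df3 <- df[, 1:4]; df3$a <- 1
  sch3 <- predictor_schema(list(
    list(name = "a", level = "person_by_item", kind = "continuous")
  ))
  expect_error(preprocess(load_long_table(df3, sch3)),
               class = "empty_feature_error")
})

test_that("preprocess is idempotent", {
  sch <- toy_schema()
  prep1 <- preprocess(load_long_table(toy_table_df(), sch))
  prep2 <- preprocess(prep1$table)
  expect_equal(as.data.frame(prep1$table), as.data.frame(prep2$table))
  expect_equal(prep1$dropped$predictor, prep2$dropped$predictor)
})

test_that("encodings have the contracted shapes", {
  sch <- toy_schema()
  prep <- preprocess(load_long_table(toy_table_df(), sch))
  X <- encode(prep, "eirm")
  # intercept + ability + effort + grade(2-1) + format(3-1)
  expect_equal(ncol(X), 1 + 2 + 1 + 2)
  expect_true(all(c("grade.g8", "format.open", "format.tf") %in% colnames(X)))
  expect_false("grade.g5" %in% colnames(X))

  F <- encode(prep, "forest")
  expect_equal(ncol(F), length(prep$schema$predictors))
  expect_true(is.factor(F$format))
  expect_equal(nlevels(F$format), 3)

  # unseen category at transform time
  nd <- as.data.frame(prep$table)[1:2, ]
  nd$format <- "essay"
  expect_error(encode(prep, "eirm", newdata = nd), class = "encoding_error")
})

test_that("newdata encoding applies stored centers", {
  sch <- toy_schema()
  prep <- preprocess(load_long_table(toy_table_df(), sch))
  nd <- toy_table_df()[1:3, ]
  X <- encode(prep, "eirm", newdata = nd)
  expect_equal(X[, "ability"],
               nd$ability - prep$centers[["ability"]],
               ignore_attr = TRUE)
})
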