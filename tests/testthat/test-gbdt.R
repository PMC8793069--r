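test_that("initial score is the loss-minimizing constant", {
  expect_equal(init_model(c(1, 0, 1, 0), "logistic"), 0)
  expect_equal(init_model(c(1, 1, 1, 0), "squared"), 0.75)
  expect_equal(init_model(c(rep(1, 9), 0), "logistic"), log(9))
  expect_error(init_model(rep(1, 5), "logistic"), "degenerate labels")
})

test_that("negative gradients follow the loss definitions", {
  expect_equal(negative_gradient(1, 0, "logistic"), 0.5)
  expect_equal(negative_gradient(2, 0.5, "squared"), 1.5)
  f <- seq(-20, 20, length.out = 101)
  r <- negative_gradient(rep(c(0, 1), length.out = 101), f, "logistic")
  expect_true(all(r > -1 & r < 1))
})

test_that("leaf values solve the per-leaf line search", {
  # squared loss: leaf mean of residuals
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  tree <- fit_regression_tree(X, c(1, 3, 10, 12), max_depth = 1)
  gam <- fit_leaf_values(tree, X, labels = c(1, 3, 10, 12),
                         f_prev = rep(0, 4), loss = "squared")
  leaves <- which(tidy(tree)$is_leaf)
  expect_setequal(gam[leaves], c(2, 11))

  # logistic: single-sample Newton step = 0.5 / 0.25 = 2
  one <- fit_regression_tree(matrix(1), 0.5, max_depth = 1)
  expect_equal(fit_leaf_values(one, matrix(1), labels = 1, f_prev = 0,
                               loss = "logistic")[1], 2)

  # saturated leaf: zero gradient and zero curvature fall back to 0
  expect_warning(
    g0 <- fit_leaf_values(one, matrix(1), labels = 1, f_prev = 100,
                          loss = "logistic"),
    "zero Newton")
  expect_equal(g0[1], 0)

  # Newton values are clipped to [-4, 4]
  big <- fit_regression_tree(matrix(1:10, ncol = 1), rep(0.9, 10),
                             max_depth = 1)
  gam_big <- fit_leaf_values(big, matrix(1:10, ncol = 1),
                             labels = rep(1, 10), f_prev = rep(-3, 10),
                             loss = "logistic")
  expect_equal(max(gam_big), 4)
})

test_that("a model with zero rounds predicts the constant score", {
  dat <- toy_binary(seed = 3)
  fit <- fit_gbdt(dat$X, dat$y, gbdt_config(n_rounds = 0))
  sc <- predict_score(fit, dat$X)
  expect_true(all(sc$score == fit$f0))
  expect_true(all(sc$probability == 1 / (1 + exp(-fit$f0))))
})

test_that("unshrunk squared-loss boosting drives training error to zero", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  y <- c(0, 0, 1, 1, 3, 3)
  fit <- fit_gbdt(X, y, gbdt_config(n_rounds = 30, learning_rate = 1,
                                    max_depth = 2, min_leaf = 1,
                                    loss = "squared"))
  expect_true(all(diff(fit$train_loss) <= 1e-12))
  expect_lt(fit$train_loss[30], 1e-10)
  expect_equal(predict(fit, X, type = "link"), y, tolerance = 1e-6)
})

test_that("one squared-loss stump reproduces the step function", {
  fit <- fit_gbdt(matrix(1:4, ncol = 1), c(0, 0, 1, 1),
                  gbdt_config(n_rounds = 1, learning_rate = 1,
                              max_depth = 1, min_leaf = 1,
                              loss = "squared"))
  expect_equal(predict(fit, matrix(1:4, ncol = 1)), c(0, 0, 1, 1))
})

test_that("training deviance never increases across rounds", {
  for (seed in 1:5) {
    dat <- toy_binary(seed = seed)
    for (nu in c(0.1, 1.0)) {
      fit <- fit_gbdt(dat$X, dat$y,
                      gbdt_config(n_rounds = 40, learning_rate = nu))
      expect_true(all(diff(fit$train_loss) <= 1e-12),
                  label = sprintf("monotone deviance (seed %d, nu %.1f)",
                                  seed, nu))
    }
  }
})

test_that("trees with all-zero leaves are additive identities", {
  dat <- toy_binary(seed = 8)
  fit <- fit_gbdt(dat$X, dat$y, gbdt_config(n_rounds = 5))
  zero_tree <- fit$trees[[1]]
  zero_tree$value <- rep(0, length(zero_tree$value))
  fit2 <- fit
  fit2$trees <- c(fit2$trees, list(zero_tree))
  expect_identical(predict(fit, dat$X), predict(fit2, dat$X))
})

test_that("fits are deterministic and invariant to sample order", {
  dat <- toy_binary(seed = 13)
  cfg <- gbdt_config(n_rounds = 15)
  fit1 <- fit_gbdt(dat$X, dat$y, cfg)
  fit2 <- fit_gbdt(dat$X, dat$y, cfg)
  expect_identical(write_gbdt(fit1), write_gbdt(fit2))

  perm <- withr::with_seed(2, sample(nrow(dat$X)))
  fit3 <- fit_gbdt(dat$X[perm, ], dat$y[perm], cfg)
  grid <- matrix(rnorm(40 * ncol(dat$X)), 40)
  expect_identical(predict(fit1, grid), predict(fit3, grid))
})

test_that("JSON serialization round-trips the model exactly", {
  dat <- toy_binary(seed = 21)
  fit <- fit_gbdt(dat$X, dat$y, gbdt_config(n_rounds = 8))
  path <- tempfile(fileext = ".json")
  write_gbdt(fit, path)
  back <- read_gbdt(path)
  expect_identical(predict(fit, dat$X), predict(back, dat$X))
  expect_identical(write_gbdt(back), write_gbdt(fit))
  expect_error(read_gbdt(jsonlite::toJSON(list(format = "other"),
                                          auto_unbox = TRUE)),
               "not a walkboost model")
})

test_that("prediction validates the feature dimension", {
  dat <- toy_binary(seed = 4)
  fit <- fit_gbdt(dat$X, dat$y, gbdt_config(n_rounds = 2))
  expect_error(predict(fit, dat$X[, 1:2]), "dimension mismatch")
})

test_that("squared-loss boosting matches an established implementation", {
  skip_if_not_installed("xgboost")
  withr::with_seed(42, {
    X <- matrix(rnorm(200 * 5), 200)
    y <- X[, 1] - 2 * X[, 2] + X[, 3] * X[, 4] + rnorm(200, sd = 0.3)
  })
  fit <- fit_gbdt(X, y, gbdt_config(n_rounds = 20, learning_rate = 0.1,
                                    max_depth = 3, min_leaf = 1,
                                    loss = "squared"))
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = 0.1, max_depth = 3,
                  lambda = 0, gamma = 0, min_child_weight = 1,
                  tree_method = "exact", base_score = mean(y)),
    data = dtrain, nrounds = 20, verbose = 0)
  ref <- predict(bst, dtrain)
  expect_lt(sqrt(mean((predict(fit, X) - ref)^2)), 1e-6)
})

test_that("model tidiers summarize rounds and configuration", {
  dat <- toy_binary(seed = 6)
  fit <- fit_gbdt(dat$X, dat$y, gbdt_config(n_rounds = 7))
  td <- tidy(fit)
  expect_equal(nrow(td), 7)
  expect_true(all(td$n_leaves >= 1))
  g <- glance(fit)
  expect_equal(g$n_trees, 7)
  expect_equal(g$final_train_loss, fit$train_loss[7])
})
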