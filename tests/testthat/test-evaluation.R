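test_that("balanced negative draws are sized, seeded and distinct", {
  pool <- sprintf("n%03d", 1:50)
  pos <- sprintf("p%03d", 1:20)

  # pool size equal to draw size: the whole pool, any seed
  full <- sample_balanced_negatives(pos, pool[1:20], n_repeats = 2, seed = 9)
  expect_true(all(vapply(full, function(d) setequal(d, pool[1:20]), TRUE)))

  draws <- sample_balanced_negatives(pos, pool, n_repeats = 5, seed = 1)
  expect_true(all(lengths(draws) == 20))
  expect_identical(draws,
                   sample_balanced_negatives(pos, pool, n_repeats = 5,
                                             seed = 1))
  expect_false(identical(draws[[1]], draws[[2]]))
  expect_error(sample_balanced_negatives(pos, pool[1:10], seed = 1),
               "smaller than")
})

test_that("stratified folds balance both classes", {
  labels <- rep(c(1, 0), each = 10)
  fold <- stratified_kfold(labels, k = 10, seed = 2)
  for (f in 1:10) {
    expect_equal(sum(labels[fold == f] == 1), 1)
    expect_equal(sum(labels[fold == f] == 0), 1)
  }
  expect_error(stratified_kfold(labels, k = 1), "at least 2")
  expect_error(stratified_kfold(rep(c(1, 0), c(5, 20)), k = 10),
               "fewer than k")

  big <- stratified_kfold(rep(c(1, 0), each = 435), k = 10, seed = 3)
  expect_true(all(table(big) == 87))
})

test_that("AUC is the Mann-Whitney concordance probability", {
  expect_equal(compute_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(compute_auc(c(1, 1, 0, 0), c(5, 4, 3, 2)), 1)
  expect_equal(compute_auc(c(1, 1, 0, 0), rep(7, 4)), 0.5)
  expect_error(compute_auc(rep(1, 4), 1:4), "both classes")
  expect_error(compute_auc(c(1, 0), c(1, NA)), "finite")
})

test_that("pair-counting AUC equals trapezoidal ROC integration", {
  for (seed in 1:30) {
    withr::with_seed(seed, {
      n <- sample(10:60, 1)
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) == 0) labels[1] <- 1
      if (sum(labels) == n) labels[n] <- 0
      scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    })
    expect_equal(compute_auc(labels, scores), auc_trapezoid(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(5, {
    labels <- rbinom(40, 1, 0.5)
    labels[1:2] <- c(0, 1)
    scores <- rnorm(40)
  })
  base <- compute_auc(labels, scores)
  expect_equal(compute_auc(labels, exp(scores)), base)
  expect_equal(compute_auc(labels, 3 * scores - 7), base)
  expect_equal(compute_auc(labels, rank(scores)), base)
})

test_that("AUPR follows the average-precision definition", {
  expect_equal(compute_aupr(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_equal(compute_aupr(c(0, 0, 0, 1), c(0.9, 0.8, 0.7, 0.1)), 0.25)
  expect_equal(compute_aupr(rep(1, 5), rnorm(5)), 1)
  expect_error(compute_aupr(rep(0, 4), 1:4), "positive")
  # tied scores are one group: both positives get precision 2/4
  expect_equal(compute_aupr(c(1, 1, 0, 0), rep(1, 4)), 0.5)
})

test_that("cross-validation hits the oracle upper bound", {
  fx <- generate_planted_module(synthetic_spec(n_disease = 20,
                                               n_background = 60, seed = 2))
  feats <- extract_features(fx$network, rwr_config())
  pos <- names(fx$labels)[fx$labels == 1]
  pool <- names(fx$labels)[fx$labels == 0]
  cv <- cross_validate(feats, pos, pool,
                       classifier_oracle(fx$labels), k = 5, n_repeats = 2,
                       seed = 3)
  g <- glance(cv)
  expect_equal(g$mean_auc, 1)
  expect_equal(g$sd_auc, 0)
  expect_equal(nrow(cv$metrics), 10)  # k x n_repeats fold-level rows
})

test_that("a random scorer sits at the null AUC", {
  withr::with_seed(17, {
    feats <- matrix(rnorm(300 * 4), 300,
                    dimnames = list(sprintf("g%03d", 1:300), NULL))
  })
  pos <- rownames(feats)[1:120]
  pool <- rownames(feats)[121:300]
  cv <- cross_validate(feats, pos, pool, classifier_random(), k = 5,
                       n_repeats = 4, seed = 11)
  expect_lt(abs(glance(cv)$mean_auc - 0.5), 0.05)
})

test_that("summary spread is the population sd across folds", {
  fx <- generate_planted_module(synthetic_spec(n_disease = 15,
                                               n_background = 45, seed = 4))
  feats <- extract_features(fx$network, rwr_config())
  pos <- names(fx$labels)[fx$labels == 1]
  pool <- names(fx$labels)[fx$labels == 0]
  cv <- cross_validate(feats, pos, pool,
                       classifier_tree(max_depth = 2, min_leaf = 2),
                       k = 3, n_repeats = 2, seed = 5)
  g <- glance(cv)
  x <- cv$metrics$auc
  expect_equal(g$sd_auc, sqrt(mean((x - mean(x))^2)))
  gse <- glance(cv, se = TRUE)
  expect_equal(gse$sd_auc, g$sd_auc / sqrt(length(x)))
  expect_identical(tidy(cv), cv$metrics)
})

test_that("cross-validation rejects genes missing from the features", {
  feats <- matrix(rnorm(20), 5, dimnames = list(paste0("g", 1:5), NULL))
  expect_error(
    cross_validate(feats, positives = c("g1", "zzz"),
                   negative_pool = paste0("g", 2:5)),
    "absent from the feature matrix")
})

test_that("curve points and plots are consistent with the metrics", {
  labels <- c(1, 0, 1, 0, 1)
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  rp <- roc_points(labels, scores)
  expect_equal(rp$fpr[1], 0)
  expect_equal(rp$tpr[nrow(rp)], 1)
  pp <- pr_points(labels, scores)
  expect_equal(pp$recall[nrow(pp)], 1)

  fx <- generate_planted_module(synthetic_spec(n_disease = 12,
                                               n_background = 36, seed = 6))
  feats <- extract_features(fx$network, rwr_config())
  pos <- names(fx$labels)[fx$labels == 1]
  cv <- cross_validate(feats, pos, setdiff(names(fx$labels), pos),
                       classifier_tree(max_depth = 2, min_leaf = 2),
                       k = 3, n_repeats = 2, seed = 8)
  expect_s3_class(autoplot(cv, type = "roc"), "ggplot")
  expect_s3_class(plot_pr(cv), "ggplot")
})
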